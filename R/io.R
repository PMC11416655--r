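# Readers/writers for every external format the pipeline touches:
# delimited gene x sample matrices, GCT 1.2/1.3 signature compendia, GMT gene
# sets, per-treatment differential-expression tables, citation tables, and the
# final candidate report. All writers round-trip losslessly through their
# paired reader (value-exact for finite floats; numbers are serialized with
# 17 significant digits).

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a gene x sample numeric matrix
#'
#' Expects one header row of column identifiers and a first column of row
#' identifiers (TSV or CSV, auto-detected). Non-numeric cells become `NA`.
#'
#' @param path file path.
#' @param rows_are_genes if `FALSE` the table is transposed after reading so
#'   genes are always on the rows of the returned matrix.
#' @return numeric matrix with unique `rownames`/`colnames`.
#' @export
read_matrix <- function(path, rows_are_genes = TRUE) {
  ft_assert(file.exists(path), sprintf("file not found: %s", path))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  ft_assert(nrow(df) > 0 && ncol(df) >= 2, sprintf("no data rows in %s", path))
  ids <- df[[1L]]
  check_unique(ids, "row identifiers")
  check_unique(colnames(df)[-1L], "column identifiers")
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(df))
  rownames(vals) <- ids
  colnames(vals) <- colnames(df)[-1L]
  if (!rows_are_genes) vals <- t(vals)
  vals
}

#' Write a gene x sample matrix as TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header of the identifier column.
#' @export
write_matrix <- function(mat, path, id_name = "id") {
  ft_assert(!is.null(rownames(mat)) && !is.null(colnames(mat)),
            "matrix must have row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

# ---- signature compendium (GCT) ----------------------------------------------

#' Construct a signature compendium
#'
#' A perturbation-signature compendium pairs a genes x signatures z-score
#' matrix with per-signature metadata (which gene was knocked down, in which
#' cell context).
#'
#' @param matrix numeric genes x signatures matrix with dimnames.
#' @param meta data.frame with columns `signature_id`, `perturbed_gene`,
#'   `cell_line`, `perturbation_type`; one row per matrix column.
#' @return object of class `signature_compendium`.
#' @export
signature_compendium <- function(matrix, meta) {
  ft_assert(is.matrix(matrix) && !is.null(colnames(matrix)),
            "matrix must have signature column names")
  check_unique(rownames(matrix), "gene identifiers")
  check_unique(colnames(matrix), "signature identifiers")
  need <- c("signature_id", "perturbed_gene", "cell_line", "perturbation_type")
  ft_assert(all(need %in% names(meta)),
            sprintf("meta must contain columns: %s", paste(need, collapse = ", ")))
  missing_meta <- setdiff(colnames(matrix), meta$signature_id)
  ft_assert(length(missing_meta) == 0,
            sprintf("signatures without metadata: %s",
                    paste(utils::head(missing_meta, 5L), collapse = ", ")))
  meta <- meta[match(colnames(matrix), meta$signature_id), need]
  bad <- meta$signature_id[is.na(meta$perturbed_gene) | meta$perturbed_gene == ""]
  if (length(bad) > 0)
    stop(sprintf("signatures lacking perturbed_gene: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  rownames(meta) <- NULL
  structure(list(matrix = matrix, meta = meta), class = "signature_compendium")
}

#' @export
print.signature_compendium <- function(x, ...) {
  cat(sprintf("signature_compendium: %d genes x %d signatures (%d perturbed genes)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$meta$perturbed_gene))))
  invisible(x)
}

#' Read a GCT 1.2/1.3 signature file
#'
#' GCT 1.3 column annotations `pert_iname`, `cell_id` and `pert_type` populate
#' the signature metadata. For GCT 1.2 (no embedded annotations) a sibling TSV
#' keyed by `signature_id` must be supplied via `meta_path`.
#'
#' @param path GCT file.
#' @param meta_path optional TSV with columns `signature_id`, `perturbed_gene`,
#'   `cell_line`, `perturbation_type`.
#' @return a [signature_compendium()].
#' @export
read_gct <- function(path, meta_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  ft_assert(length(lines) >= 3, sprintf("truncated GCT file: %s", path))
  version <- trimws(lines[1L])
  if (!version %in% c("#1.2", "#1.3"))
    stop(sprintf("unsupported GCT version line '%s' (expected #1.2 or #1.3)", version),
         call. = FALSE)
  dims <- as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]])
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1L]]

  if (version == "#1.2") {
    nr <- dims[1L]; nc <- dims[2L]
    header <- split_row(lines[3L])
    sig_ids <- header[-(1:2)]
    body <- lines[3L + seq_len(nr)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    gene_ids <- vapply(parts, `[[`, "", 1L)
    vals <- t(vapply(parts, function(p) as.numeric(p[-(1:2)]), numeric(nc)))
    ft_assert(length(sig_ids) == nc, "GCT column count does not match dimension line")
    ft_assert(length(gene_ids) == nr, "GCT row count does not match dimension line")
    ft_assert(!is.null(meta_path),
              "GCT 1.2 carries no column annotations; supply meta_path")
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    nr <- dims[1L]; nc <- dims[2L]; nrm <- dims[3L]; ncm <- dims[4L]
    header <- split_row(lines[3L])
    sig_ids <- header[-seq_len(1L + nrm)]
    ft_assert(length(sig_ids) == nc, "GCT column count does not match dimension line")
    ann_lines <- lines[3L + seq_len(ncm)]
    ann <- list()
    for (ln in ann_lines) {
      p <- split_row(ln)
      a <- p[-seq_len(1L + nrm)]
      length(a) <- nc                     # strsplit drops trailing empties
      a[is.na(a)] <- ""
      ann[[p[1L]]] <- a
    }
    body <- lines[3L + ncm + seq_len(nr)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    gene_ids <- vapply(parts, `[[`, "", 1L)
    vals <- t(vapply(parts, function(p) as.numeric(p[-seq_len(1L + nrm)]), numeric(nc)))
    ft_assert(length(gene_ids) == nr, "GCT row count does not match dimension line")
    if (!is.null(meta_path)) {
      meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      meta <- data.frame(
        signature_id = sig_ids,
        perturbed_gene = ann[["pert_iname"]] %||% rep("", nc),
        cell_line = ann[["cell_id"]] %||% rep(NA_character_, nc),
        perturbation_type = ann[["pert_type"]] %||% rep(NA_character_, nc),
        stringsAsFactors = FALSE
      )
    }
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sig_ids
  signature_compendium(vals, meta)
}

#' Write a signature compendium as GCT 1.3
#'
#' Metadata is embedded as the column annotations `pert_iname`, `cell_id`,
#' `pert_type`, so [read_gct()] recovers the full compendium.
#'
#' @param compendium a [signature_compendium()].
#' @param path output path.
#' @export
write_gct <- function(compendium, path) {
  m <- compendium$matrix
  meta <- compendium$meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(sprintf("%d\t%d\t0\t3", nrow(m), ncol(m)), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(c("pert_iname", meta$perturbed_gene), collapse = "\t"), con)
  writeLines(paste(c("cell_id", meta$cell_line), collapse = "\t"), con)
  writeLines(paste(c("pert_type", meta$perturbation_type), collapse = "\t"), con)
  body <- apply(m, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

# ---- gene sets (GMT) ---------------------------------------------------------

#' Construct a gene set
#'
#' @param name set name.
#' @param members character vector of gene ids (duplicates removed).
#' @param direction `"up"`, `"down"` or `"none"`.
#' @param description free-text description.
#' @export
gene_set <- function(name, members, direction = "none", description = "") {
  members <- unique(as.character(members))
  ft_assert(length(members) >= 1, sprintf("gene set '%s' has no members", name))
  ft_assert(direction %in% c("up", "down", "none"), "invalid direction")
  structure(list(name = name, direction = direction, members = members,
                 description = description), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: name, description, then tab-separated members. Lines with no
#' members are skipped with a warning.
#'
#' @param path GMT file.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (length(p) < 3 || length(members) == 0) {
      warning(sprintf("GMT set '%s' has no members; skipped", p[1L]), call. = FALSE)
      next
    }
    sets[[p[1L]]] <- gene_set(p[1L], members, description = p[2L])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description %||% "", s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# ---- differential-expression profiles ----------------------------------------

#' Construct a fold-change profile
#'
#' One per-treatment differential-expression table: gene-level log2 fold
#' changes (inducer vs. control), with optional p-values.
#'
#' @param profile_id identifier (conventionally `cellline_drug`).
#' @param gene character vector of unique gene ids.
#' @param log2fc numeric log2 fold changes.
#' @param p_value optional numeric p-values in \[0, 1\].
#' @export
fc_profile <- function(profile_id, gene, log2fc, p_value = NULL) {
  check_unique(gene, sprintf("gene ids in profile %s", profile_id))
  ft_assert(length(gene) == length(log2fc), "gene/log2fc length mismatch")
  if (!is.null(p_value)) {
    ft_assert(length(p_value) == length(gene), "gene/p_value length mismatch")
    ok <- is.na(p_value) | (p_value >= 0 & p_value <= 1)
    ft_assert(all(ok), sprintf("p-values outside [0,1] in profile %s", profile_id))
  }
  df <- data.frame(gene = as.character(gene), log2fc = as.numeric(log2fc),
                   stringsAsFactors = FALSE)
  if (!is.null(p_value)) df$p_value <- as.numeric(p_value)
  structure(df, profile_id = profile_id, class = c("fc_profile", "data.frame"))
}

#' Read a differential-expression table (gene, log2fc\[, p_value\])
#'
#' @param path TSV/CSV with columns `gene`, `log2fc` and optionally `p_value`
#'   (aliases `log2FC`/`logFC` and `pvalue`/`P.Value` are accepted).
#' @param profile_id identifier; defaults to the file stem.
#' @export
read_fc_profile <- function(path, profile_id = NULL) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- tolower(names(df))
  gcol <- match(TRUE, nm %in% c("gene", "gene_id", "symbol"))
  fcol <- match(TRUE, nm %in% c("log2fc", "logfc", "log2foldchange"))
  pcol <- match(TRUE, nm %in% c("p_value", "pvalue", "p.value", "pval"))
  ft_assert(!is.na(gcol) && !is.na(fcol),
            sprintf("%s lacks gene/log2fc columns", path))
  fc_profile(profile_id %||% sub("\\.[^.]+$", "", basename(path)),
             df[[gcol]], df[[fcol]],
             if (!is.na(pcol)) df[[pcol]] else NULL)
}

#' Write a fold-change profile as TSV
#' @param profile an [fc_profile()].
#' @param path output path.
#' @export
write_fc_profile <- function(profile, path) {
  utils::write.table(format(as.data.frame(profile), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- citation table ----------------------------------------------------------

#' Read an offline gene x term citation-count table
#'
#' Long-format TSV with columns `gene`, `term`, `count`; genes absent from the
#' table are treated as uncited downstream.
#'
#' @param path TSV path.
#' @return data.frame of class `citation_table` with a `terms` attribute.
#' @export
read_citation_table <- function(path) {
  df <- utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ft_assert(all(c("gene", "term", "count") %in% names(df)),
            "citation table needs columns gene, term, count")
  citation_table(df)
}

#' Construct a citation table
#' @param df data.frame with columns `gene`, `term`, `count` (counts >= 0).
#' @export
citation_table <- function(df) {
  ft_assert(all(df$count >= 0), "citation counts must be non-negative")
  check_unique(paste(df$gene, df$term, sep = "\r"), "gene-term pairs")
  structure(df, terms = sort(unique(df$term)),
            class = c("citation_table", "data.frame"))
}

#' Write a citation table as TSV
#' @param table a `citation_table`.
#' @param path output path.
#' @export
write_citation_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- final report ------------------------------------------------------------

#' Write the ranked candidate report
#'
#' Rows are sorted by ascending anchor distance (ties by gene id) and the
#' `rank` column rewritten as 1..n in that order, so the written report is
#' deterministic regardless of input row order.
#'
#' @param ranked_table data.frame with at least `gene` and `distance` columns;
#'   predictor values and filter flags are carried through.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(ranked_table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  ft_assert(all(c("gene", "distance") %in% names(ranked_table)),
            "report needs gene and distance columns")
  ord <- order(ranked_table$distance, ranked_table$gene)
  tab <- ranked_table[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  lead <- c("gene", "distance", "rank")
  tab <- tab[, c(lead, setdiff(names(tab), lead)), drop = FALSE]
  rownames(tab) <- NULL
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
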