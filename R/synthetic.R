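# Synthetic benchmark world with planted ground-truth suppressors.
#
# The generator emits a self-consistent world at the level the pipeline
# consumes (viability curves, expression/dependency matrices, fold-change
# profiles with p-values, a knockdown signature compendium, a citation
# table). One latent per-line resistance v_l drives the drug AUCs; planted
# suppressor genes have expression and dependency calibrated to correlate
# with v (hence with the AUCs), and their knockdown signatures mimic a latent
# inducer-response vector f shared by all fold-change profiles. Everything
# else is noise. One master seed feeds positionally fixed per-table streams,
# so the world is bit-reproducible and adding a table never perturbs another.

#' Configuration of a synthetic world
#'
#' Defaults state a desk-scale analogue of the published inputs: 16 cell
#' lines with 3 drugs (as in the vulnerability screen), 10 fold-change
#' profiles (5 treated lines x 2 inducers), knockdown signatures over 4-9
#' cell contexts per gene, 500 knocked-down genes (scaled down from 3932),
#' planted correlation strength 0.7 (just above the 0.65 reporting
#' threshold) and signature mimic strength 0.8.
#'
#' @param n_genes gene universe size G.
#' @param n_cell_lines number of cell lines L.
#' @param n_drugs number of drugs (<= 3 named inducers).
#' @param n_profiles number of fold-change profiles M.
#' @param n_kd_genes number of knocked-down genes in the compendium.
#' @param cell_lines_per_kd range of cell contexts per knockdown.
#' @param n_planted number of planted suppressors besides the anchor.
#' @param planted_corr_strength target |Pearson r| of planted expression and
#'   dependency with the latent resistance axis.
#' @param signature_mimic_strength correlation of a planted knockdown
#'   signature with the latent inducer response.
#' @param noise_sd noise multiplier; 0 gives exactly collinear planted genes.
#' @param seed master seed.
#' @return named list of class `world_config`.
#' @export
world_config <- function(n_genes = 2000L, n_cell_lines = 16L, n_drugs = 3L,
                         n_profiles = 10L, n_kd_genes = 500L,
                         cell_lines_per_kd = c(4L, 9L), n_planted = 20L,
                         planted_corr_strength = 0.7,
                         signature_mimic_strength = 0.8,
                         noise_sd = 1, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_lines = as.integer(n_cell_lines),
              n_drugs = as.integer(n_drugs),
              n_profiles = as.integer(n_profiles),
              n_kd_genes = as.integer(n_kd_genes),
              cell_lines_per_kd = as.integer(cell_lines_per_kd),
              n_planted = as.integer(n_planted),
              planted_corr_strength = planted_corr_strength,
              signature_mimic_strength = signature_mimic_strength,
              noise_sd = noise_sd, seed = as.integer(seed))
  ft_assert(cfg$n_genes >= cfg$n_planted + 1, "universe too small for planted genes")
  ft_assert(cfg$n_kd_genes >= cfg$n_planted + 1 && cfg$n_kd_genes <= cfg$n_genes,
            "n_kd_genes must cover planted genes and fit in the universe")
  ft_assert(cfg$planted_corr_strength > 0 && cfg$planted_corr_strength < 1,
            "planted_corr_strength must be in (0, 1)")
  ft_assert(cfg$signature_mimic_strength > 0 && cfg$signature_mimic_strength < 1,
            "signature_mimic_strength must be in (0, 1)")
  ft_assert(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  ft_assert(cfg$n_profiles >= 1 && cfg$n_cell_lines >= 4, "world too small")
  structure(cfg, class = "world_config")
}

.drug_names <- c("erastin", "RSL3", "FIN56")
.ferro_terms <- c("Ferroptosis", "Glutathione", "GPX4", "Iron",
                  "Lipid Peroxidation", "SLC7A11")

#' Generate a synthetic world
#'
#' See the package vignette for the generative model. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world` with elements `viability`,
#'   `expression`, `dependency`, `profiles`, `compendium`, `citations`,
#'   `truth` (planted genes, anchor, latent resistance and response vectors,
#'   true AUC matrix) and `config`.
#' @export
generate_world <- function(config = world_config()) {
  cfg <- config
  streams <- derive_seeds(cfg$seed, 8L)
  G <- cfg$n_genes; L <- cfg$n_cell_lines
  planted <- c("ANCHOR1", sprintf("SUP%02d", seq_len(cfg$n_planted)))
  genes <- c(planted, sprintf("G%04d", seq_len(G - length(planted))))
  lines <- sprintf("CL%02d", seq_len(L))
  drugs <- .drug_names[seq_len(cfg$n_drugs)]
  rho <- cfg$planted_corr_strength
  mimic <- cfg$signature_mimic_strength
  nsd <- cfg$noise_sd

  # stream 1: latent resistance, dose-response curves, true AUCs
  lat <- with_seed(streams[1L], {
    v <- as.vector(scale(stats::rnorm(L)))
    names(v) <- lines
    doses <- 10^seq(-2, 1, length.out = 8)
    viab <- list(); auc_true <- matrix(NA_real_, L, length(drugs),
                                       dimnames = list(lines, drugs))
    k <- 0L
    for (dr in drugs) {
      drug_shift <- stats::runif(1, -0.3, 0.3)
      for (l in lines) {
        le <- -0.5 + drug_shift + 0.45 * v[l] + 0.1 * stats::rnorm(1)
        e <- 10^le
        fit <- structure(list(b = 1.5, c = 5, d = 100, e = e,
                              dose_range = range(doses),
                              degenerate = FALSE),
                         class = "dose_response_fit")
        auc_true[l, dr] <- compute_auc(fit)
        for (rep_i in 1:3) {
          k <- k + 1L
          viab[[k]] <- data.frame(
            cell_line = l, drug = dr, dose = doses, replicate = rep_i,
            viability = pmax(0, ll4(doses, 1.5, 5, 100, e) +
                               nsd * 4 * stats::rnorm(length(doses))),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(v = v, viability = do.call(rbind, viab), auc_true = auc_true)
  })
  v <- lat$v

  planted_row <- function(latent, strength, noise) {
    strength * latent + noise * sqrt(1 - strength^2)
  }

  # stream 2: expression (planted rows track v; background pure noise)
  expression <- with_seed(streams[2L], {
    m <- matrix(stats::rnorm(G * L), G, L, dimnames = list(genes, lines))
    for (g in planted)
      m[g, ] <- planted_row(v, rho, nsd * stats::rnorm(L))
    m
  })

  # stream 3: dependency (planted rows track v; a few pan-essential genes)
  dependency <- with_seed(streams[3L], {
    m <- matrix(stats::rnorm(G * L, mean = -0.1, sd = 0.3), G, L,
                dimnames = list(genes, lines))
    for (g in planted)
      m[g, ] <- planted_row(v, rho, nsd * stats::rnorm(L))
    n_ess <- max(1L, round(0.02 * (G - length(planted))))
    ess <- sprintf("G%04d", seq_len(n_ess))
    m[ess, ] <- matrix(stats::rnorm(n_ess * L, mean = -1, sd = 0.1), n_ess, L)
    m
  })

  # stream 4: latent inducer response + M fold-change profiles with 2v2
  # replicate t-test p-values
  prof <- with_seed(streams[4L], {
    f <- stats::rnorm(G)
    names(f) <- genes
    prof_lines <- lines[seq_len(ceiling(cfg$n_profiles / 2))]
    prof_drugs <- .drug_names[1:2]
    ids <- as.vector(outer(prof_lines, prof_drugs, paste, sep = "_"))[seq_len(cfg$n_profiles)]
    rep_sd <- 0.5 * max(nsd, 0.1)
    profiles <- lapply(ids, function(id) {
      fc <- f + nsd * 0.6 * stats::rnorm(G)
      ctrl <- matrix(stats::rnorm(G * 2, 0, rep_sd), G, 2)
      trt <- matrix(stats::rnorm(G * 2, fc, rep_sd), G, 2)
      md <- rowMeans(trt) - rowMeans(ctrl)
      s2 <- (apply(trt, 1L, stats::var) + apply(ctrl, 1L, stats::var)) / 2
      tstat <- md / sqrt(s2 * (1 / 2 + 1 / 2))
      p <- 2 * stats::pt(-abs(tstat), df = 2)
      fc_profile(id, genes, fc, p)
    })
    names(profiles) <- ids
    list(f = f, profiles = profiles)
  })
  f_std <- as.vector(scale(prof$f))
  names(f_std) <- genes

  # stream 5: knockdown gene selection + signature compendium
  compendium <- with_seed(streams[5L], {
    background <- setdiff(genes, planted)
    kd_genes <- c(planted,
                  sort(sample(background, cfg$n_kd_genes - length(planted))))
    sig_ids <- character(0); sig_gene <- character(0); sig_line <- character(0)
    cols <- list()
    for (g in kd_genes) {
      n_ctx <- sample(seq(cfg$cell_lines_per_kd[1L], cfg$cell_lines_per_kd[2L]), 1L)
      n_ctx <- min(n_ctx, L)
      ctx <- sort(sample(lines, n_ctx))
      for (cl in ctx) {
        sig_ids <- c(sig_ids, paste(g, cl, sep = ":"))
        sig_gene <- c(sig_gene, g); sig_line <- c(sig_line, cl)
        z <- if (g %in% planted)
          planted_row(f_std, mimic, nsd * stats::rnorm(G))
        else stats::rnorm(G)
        cols[[length(cols) + 1L]] <- z
      }
    }
    m <- do.call(cbind, cols)
    dimnames(m) <- list(genes, sig_ids)
    signature_compendium(m, data.frame(
      signature_id = sig_ids, perturbed_gene = sig_gene, cell_line = sig_line,
      perturbation_type = "trt_sh.cgs", stringsAsFactors = FALSE))
  })

  # stream 6: citation table (planted genes enriched for nonzero counts)
  citations <- with_seed(streams[6L], {
    rows <- list()
    for (g in genes) {
      p_hit <- if (g %in% planted) 0.6 else 0.05
      hit <- stats::runif(length(.ferro_terms)) < p_hit
      if (!any(hit)) next
      counts <- 1L + stats::rpois(sum(hit), if (g %in% planted) 4 else 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, term = .ferro_terms[hit], count = counts,
        stringsAsFactors = FALSE)
    }
    citation_table(do.call(rbind, rows))
  })

  structure(list(
    viability = lat$viability,
    expression = expression,
    dependency = dependency,
    profiles = prof$profiles,
    compendium = compendium,
    citations = citations,
    truth = list(planted = planted, anchor = "ANCHOR1", latent_resistance = v,
                 latent_response = prof$f, auc_true = lat$auc_true),
    config = cfg), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d genes x %d lines, %d profiles, %d signatures, %d planted (+anchor %s)\n",
    x$config$n_genes, x$config$n_cell_lines, length(x$profiles),
    ncol(x$compendium$matrix), x$config$n_planted, x$truth$anchor))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits every table in the format the corresponding reader consumes, plus a
#' `manifest.json` recording the paths, seed and config.
#'
#' @param world a [generate_world()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
world_to_files <- function(world, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  utils::write.table(world$viability, p("viability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(world$expression, p("expression.tsv"), id_name = "gene")
  write_matrix(world$dependency, p("dependency.tsv"), id_name = "gene")
  dir.create(p("profiles"), showWarnings = FALSE)
  prof_paths <- vapply(world$profiles, function(pr) {
    path <- p("profiles", paste0(attr(pr, "profile_id"), ".tsv"))
    write_fc_profile(pr, path)
    path
  }, "")
  write_gct(world$compendium, p("signatures.gct"))
  write_citation_table(world$citations, p("citations.tsv"))
  jsonlite::write_json(world$truth[c("planted", "anchor")], p("truth.json"),
                       auto_unbox = TRUE)
  manifest <- list(
    seed = world$config$seed,
    config = unclass(world$config),
    files = list(viability = p("viability.tsv"),
                 expression = p("expression.tsv"),
                 dependency = p("dependency.tsv"),
                 profiles = as.list(unname(prof_paths)),
                 signatures = p("signatures.gct"),
                 citations = p("citations.tsv"),
                 truth = p("truth.json")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a synthetic world back from a manifest
#'
#' @param dir directory containing `manifest.json` from [world_to_files()].
#' @return a `synthetic_world`-shaped list (without latent truth vectors).
#' @export
read_world <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fl <- manifest$files
  profiles <- lapply(unlist(fl$profiles), read_fc_profile)
  names(profiles) <- vapply(profiles, function(p) attr(p, "profile_id"), "")
  truth <- jsonlite::read_json(fl$truth, simplifyVector = TRUE)
  structure(list(
    viability = utils::read.table(fl$viability, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE),
    expression = read_matrix(fl$expression),
    dependency = read_matrix(fl$dependency),
    profiles = profiles,
    compendium = read_gct(fl$signatures),
    citations = read_citation_table(fl$citations),
    truth = truth,
    config = manifest$config), class = "synthetic_world")
}
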