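#' Default pipeline configuration
#'
#' All stage parameters at the study defaults: missing-data thresholds
#' \{0.10, ..., 0.70\}, MAF cut-off 0.025, 90/10 cross-validation with 500
#' repetitions, Gibbs chains 5000/500/5, SVR `C = 1`, `epsilon = 0.1`, RFR
#' 500 trees / `mtry = p/3` / node size 5, RFI `ntree = 100`,
#' `maxiter = 10`, and 1- vs 5-year selection cycles.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = character(0),
    simulate = list(n_individuals_a = 124L, n_individuals_b = 154L,
                    n_markers = 5000L, n_qtl = 100L, h2 = 0.21,
                    ploidy = "tetraploid-collapsed",
                    shared_qtl_fraction = 1, freq_divergence = 0.05,
                    missing_beta_shape1 = 1, missing_beta_shape2 = 2),
    trial = list(replications = 2L, s2_hs = 1, s2_e = 2),
    qc = list(thresholds = missing_threshold_grid(), threshold = 0.3,
              imputer = "MNI", maf_min = 0.025, joint = FALSE,
              svdi_k = 10L, rfi_ntree = 100L, rfi_maxiter = 10L),
    cv = list(models = "rrBLUP", train_frac = 0.9, n_reps = 500L),
    bayes = list(n_iter = 5000L, burn_in = 500L, thin = 5L),
    svr = list(C = 1, epsilon = 0.1),
    rfr = list(n_trees = 500L, min_node = 5L),
    gwas = list(population = "a"),
    gain = list(cycle_gs = 1, cycle_conv = 5)
  )
}

check_known_keys <- function(x, template, path = "") {
  for (k in names(x)) {
    if (!k %in% names(template)) {
      stop("unknown config key: ", paste0(path, k))
    }
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(x[[k]])) stop("config key ", paste0(path, k),
                                 " must be a block")
      check_known_keys(x[[k]], template[[k]], paste0(path, k, "$"))
    }
  }
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML string, the path of a YAML file, or a named list; rejects
#' unknown keys (reporting their path) and out-of-range values, injects the
#' study defaults for everything unspecified, and resolves one explicit
#' seed per stochastic stage by name-based derivation from the master seed,
#' so that adding a stage never perturbs the seeds of others.
#'
#' @param raw YAML text, YAML file path, or named list.
#' @return an object of class `run_config`: the resolved configuration with
#'   a `stage_seeds` element and a `config_hash` fingerprint.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) {
    user <- if (length(raw) == 1L && file.exists(raw)) {
      yaml::read_yaml(raw)
    } else {
      yaml::yaml.load(paste(raw, collapse = "\n"))
    }
    user <- user %||% list()
  } else {
    user <- raw
  }
  defaults <- default_config()
  check_known_keys(user, defaults)
  cfg <- merge_config(defaults, user)

  bad <- character(0)
  if (!all(cfg$qc$thresholds > 0 & cfg$qc$thresholds < 1)) {
    bad <- c(bad, "qc$thresholds")
  }
  if (cfg$qc$threshold <= 0 || cfg$qc$threshold >= 1) bad <- c(bad, "qc$threshold")
  if (cfg$qc$maf_min < 0 || cfg$qc$maf_min > 0.5) bad <- c(bad, "qc$maf_min")
  if (cfg$simulate$h2 < 0 || cfg$simulate$h2 > 1) bad <- c(bad, "simulate$h2")
  if (cfg$cv$train_frac <= 0 || cfg$cv$train_frac >= 1) bad <- c(bad, "cv$train_frac")
  if (cfg$bayes$burn_in >= cfg$bayes$n_iter) bad <- c(bad, "bayes$burn_in")
  if (cfg$trial$replications < 1) bad <- c(bad, "trial$replications")
  known_stages <- c("simulate", "blup", "qc", "cv", "crosspop", "gwas", "gain")
  if (!all(cfg$stages %in% known_stages)) {
    bad <- c(bad, paste0("stages (must be among ",
                         paste(known_stages, collapse = ", "), ")"))
  }
  if (length(bad) > 0L) {
    stop("out-of-range or invalid config values: ", paste(bad, collapse = ", "))
  }
  cfg$stage_seeds <- stats::setNames(
    lapply(known_stages, function(s) derive_seed(cfg$seed, s)), known_stages)
  h <- fnv1a32(paste(
    utils::capture.output(utils::str(cfg, give.head = FALSE)), collapse = "\n"))
  cfg$config_hash <- sprintf("%04X%04X", as.integer(h %/% 65536),
                             as.integer(h %% 65536))
  class(cfg) <- "run_config"
  cfg
}

#' Run the genomic-selection pipeline end to end
#'
#' Executes the selected stages on two synthetic reference populations and
#' writes tab-separated result tables plus a machine-readable
#' `manifest.json` (configuration echo and hash, derived stage seeds,
#' row/marker counts per stage) to `out_dir`.  An empty stage list writes
#' the manifest only.  Identical configurations reproduce byte-identical
#' tables.
#'
#' Stage order: `simulate` (two populations + missing-data masks) ->
#' `blup` (progeny trials and BLUP-adjusted phenotypes) -> `qc` (filter /
#' impute / MAF) -> `cv` (intra-population cross-validation) -> `crosspop`
#' (COMMON set + cross-population accuracy) -> `gwas` -> `gain`.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = tempfile("gsrun")) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$stage_seeds
  manifest <- list(config_hash = config$config_hash,
                   stage_seeds = seeds,
                   stages = config$stages, counts = list())
  state <- list()

  if ("simulate" %in% config$stages) {
    sc <- config$simulate
    mk_spec <- function(n, seed) {
      population_spec(n, sc$n_markers, sc$n_qtl, h2 = sc$h2,
                      ploidy_mode = sc$ploidy, seed = seed)
    }
    pops <- simulate_two_populations(
      mk_spec(sc$n_individuals_a, derive_seed(seeds$simulate, "a")),
      mk_spec(sc$n_individuals_b, derive_seed(seeds$simulate, "b")),
      shared_qtl_fraction = sc$shared_qtl_fraction,
      freq_divergence = sc$freq_divergence,
      seed = seeds$simulate)
    law <- missing_rate_beta(sc$missing_beta_shape1, sc$missing_beta_shape2)
    state$pops <- pops
    state$masked <- list(
      a = mask_missing(pops$a$genotypes, law,
                       seed = derive_seed(seeds$simulate, "mask_a")),
      b = mask_missing(pops$b$genotypes, law,
                       seed = derive_seed(seeds$simulate, "mask_b")))
    for (p in c("a", "b")) {
      write_genotype_tsv(state$masked[[p]],
                         file.path(out_dir, paste0("genotypes_", p, ".tsv")))
      write_phenotype_tsv(pops[[p]]$phenotype,
                          file.path(out_dir, paste0("phenotype_", p, ".tsv")))
    }
    manifest$counts$simulate <- list(
      n_individuals = c(a = nrow(pops$a$genotypes),
                        b = nrow(pops$b$genotypes)),
      n_markers = ncol(pops$a$genotypes))
  }

  if ("blup" %in% config$stages) {
    stopifnot(!is.null(state$pops))
    tc <- config$trial
    state$adjusted <- list()
    for (p in c("a", "b")) {
      trial <- simulate_progeny_trial(
        state$pops[[p]]$model$breeding_values,
        r = tc$replications, s2_hs = tc$s2_hs, s2_e = tc$s2_e,
        seed = derive_seed(seeds$blup, p))
      adj <- blup_phenotypes(trial)
      state$adjusted[[p]] <- adj
      write_trial_tsv(trial, file.path(out_dir, paste0("trial_", p, ".tsv")))
      write_phenotype_tsv(adj, file.path(out_dir,
                                         paste0("phenotype_blup_", p, ".tsv")))
    }
    manifest$counts$blup <- lapply(state$adjusted, function(a)
      list(n_progenies = length(a), h_B2 = attr(a, "h_B2")))
  }

  if ("qc" %in% config$stages) {
    stopifnot(!is.null(state$masked))
    qcc <- config$qc
    params <- list(k = qcc$svdi_k, ntree = qcc$rfi_ntree,
                   maxiter = qcc$rfi_maxiter)
    if (qcc$joint) {
      state$imputed <- qc_pipeline(state$masked, threshold = qcc$threshold,
                                   imputer = qcc$imputer,
                                   maf_min = qcc$maf_min, joint = TRUE,
                                   params = params, seed = seeds$qc)
    } else {
      state$imputed <- lapply(state$masked, qc_pipeline,
                              threshold = qcc$threshold,
                              imputer = qcc$imputer, maf_min = qcc$maf_min,
                              params = params, seed = seeds$qc)
    }
    for (p in c("a", "b")) {
      write_genotype_tsv(state$imputed[[p]],
                         file.path(out_dir, paste0("genotypes_qc_", p, ".tsv")))
      utils::write.table(attr(state$imputed[[p]], "qc_report"),
                         file.path(out_dir, paste0("qc_report_", p, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$counts$qc <- lapply(state$imputed, ncol)
  }

  phenos <- function(p) {
    if (!is.null(state$adjusted)) as.numeric(state$adjusted[[p]])
    else state$pops[[p]]$phenotype
  }

  if ("cv" %in% config$stages) {
    stopifnot(!is.null(state$imputed))
    rows <- list()
    for (p in c("a", "b")) {
      for (mdl in config$cv$models) {
        rep_ <- cross_validate(state$imputed[[p]], phenos(p), model = mdl,
                               train_frac = config$cv$train_frac,
                               n_reps = config$cv$n_reps,
                               seed = derive_seed(seeds$cv, paste0(p, mdl)))
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, model = mdl, n_markers = ncol(state$imputed[[p]]),
          mean_r = rep_$mean_r, sd_r = rep_$sd_r, n_reps = rep_$n_reps)
      }
    }
    state$cv <- do.call(rbind, rows)
    utils::write.table(state$cv, file.path(out_dir, "cv_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$cv <- nrow(state$cv)
  }

  if ("crosspop" %in% config$stages) {
    stopifnot(!is.null(state$imputed))
    common <- build_common(state$imputed$a, state$imputed$b)
    mdl <- config$cv$models[1L]
    res <- data.frame(
      direction = c("a_predicts_b", "b_predicts_a"),
      model = mdl,
      n_markers = ncol(common$a),
      accuracy = c(
        cross_population_predict(common$a, phenos("a"), common$b, phenos("b"),
                                 model = mdl, seed = seeds$crosspop),
        cross_population_predict(common$b, phenos("b"), common$a, phenos("a"),
                                 model = mdl, seed = seeds$crosspop)))
    state$crosspop <- res
    utils::write.table(res, file.path(out_dir, "crosspop_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$crosspop <- list(n_common_markers = ncol(common$a))
  }

  if ("gwas" %in% config$stages) {
    stopifnot(!is.null(state$imputed))
    p <- config$gwas$population
    res <- mixed_model_gwas(state$imputed[[p]], phenos(p))
    tab <- manhattan_export(res)
    utils::write.table(tab, file.path(out_dir, "gwas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$gwas <- nrow(tab)
  }

  if ("gain" %in% config$stages) {
    r_A <- if (!is.null(state$cv)) max(state$cv$mean_r) else 0.32
    h_N2 <- config$simulate$h2
    g <- gain_ratio(max(r_A, 1e-6), h_N2,
                    cycle_gs = config$gain$cycle_gs,
                    cycle_conv = config$gain$cycle_conv)
    utils::write.table(
      data.frame(r_A = g$r_A, h_N = g$h_N, cycle_gs = g$cycle_gs,
                 cycle_conv = g$cycle_conv, ratio = g$ratio),
      file.path(out_dir, "gain_comparison.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$gain <- g$ratio
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(manifest_to_json(manifest), manifest_path)
  invisible(manifest)
}

# Minimal JSON rendering for the run manifest (numbers, strings, lists).
manifest_to_json <- function(x) {
  render <- function(v) {
    if (is.list(v)) {
      if (is.null(names(v))) {
        paste0("[", paste(vapply(v, render, character(1)), collapse = ","), "]")
      } else {
        paste0("{", paste(sprintf("\"%s\":%s", names(v),
                                  vapply(v, render, character(1))),
                          collapse = ","), "}")
      }
    } else if (is.character(v)) {
      if (length(v) == 0L) "[]"
      else if (length(v) == 1L) sprintf("\"%s\"", v)
      else paste0("[", paste(sprintf("\"%s\"", v), collapse = ","), "]")
    } else {
      if (length(v) == 0L) "[]"
      else if (length(v) == 1L) format(v, scientific = FALSE, digits = 10)
      else paste0("[", paste(format(v, scientific = FALSE, digits = 10),
                             collapse = ","), "]")
    }
  }
  render(x)
}
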