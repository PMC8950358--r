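#' Per-knee wide feature matrix for a classification variant
#'
#' Aggregates the (recording, segment, channel)-level feature table to one
#' row per knee for the requested kinematic chain(s). With
#' `aggregate = "mean"` the two channels and all segments are averaged per
#' measure; with `aggregate = "channel"` the medial and lateral channels
#' stay separate columns. For multi-chain variants the chains' columns are
#' concatenated with a chain prefix, keeping knees recorded in every
#' requested chain.
#'
#' @param feature_table Output of [build_feature_table()].
#' @param chains Character vector of chains, e.g. `"CKC"` or
#'   `c("CKC", "OKC")`.
#' @param aggregate `"mean"` or `"channel"`.
#' @return A list: `signal` (numeric matrix of signal measures), `demo`
#'   (data.frame `age`, `sex`, `bmi`), `y` (group labels), `knee_id`.
#' @export
variant_feature_matrix <- function(feature_table, chains,
                                   aggregate = c("mean", "channel")) {
  aggregate <- match.arg(aggregate)
  feature_table$knee_id <- paste(feature_table$subject_id,
                                 feature_table$knee, sep = "_")
  per_chain <- lapply(chains, function(ch) {
    sub <- feature_table[feature_table$chain == ch, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no rows for chain ", ch)
    if (aggregate == "mean") {
      agg <- stats::aggregate(sub[, FEATURE_NAMES],
                              by = list(knee_id = sub$knee_id), mean)
      cols <- FEATURE_NAMES
    } else {
      med <- stats::aggregate(sub[sub$channel == "medial", FEATURE_NAMES],
                              by = list(knee_id = sub$knee_id[sub$channel == "medial"]),
                              mean)
      lat <- stats::aggregate(sub[sub$channel == "lateral", FEATURE_NAMES],
                              by = list(knee_id = sub$knee_id[sub$channel == "lateral"]),
                              mean)
      names(med)[-1L] <- paste0("medial_", FEATURE_NAMES)
      names(lat)[-1L] <- paste0("lateral_", FEATURE_NAMES)
      agg <- merge(med, lat, by = "knee_id")
      cols <- c(paste0("medial_", FEATURE_NAMES),
                paste0("lateral_", FEATURE_NAMES))
    }
    if (length(chains) > 1L)
      names(agg)[-1L] <- paste0(tolower(ch), "_", names(agg)[-1L])
    agg
  })
  wide <- Reduce(function(a, b) merge(a, b, by = "knee_id"), per_chain)
  meta <- feature_table[!duplicated(feature_table$knee_id),
                        c("knee_id", "age", "sex", "bmi", "group")]
  wide <- merge(wide, meta, by = "knee_id")
  wide <- wide[order(wide$knee_id), ]
  sig_cols <- setdiff(names(wide), c("knee_id", "age", "sex", "bmi", "group"))
  list(signal = as.matrix(wide[, sig_cols, drop = FALSE]),
       demo = wide[, c("age", "sex", "bmi")],
       y = wide$group, knee_id = wide$knee_id)
}

#' Assemble classifier inputs for a variant
#'
#' `X = [age, sex code, BMI]` followed by the selected signal measures of
#' the variant's chain(s). Column order is stable: demographics first, then
#' the selected measures in their original order.
#'
#' @inheritParams variant_feature_matrix
#' @param selected Integer indices into the variant's signal-measure
#'   columns (as produced by NCA selection on [variant_feature_matrix()]
#'   output).
#' @return A list `X` (numeric matrix), `y`, `knee_id`.
#' @export
assemble_variant_inputs <- function(feature_table, chains, selected,
                                    aggregate = c("mean", "channel")) {
  vfm <- variant_feature_matrix(feature_table, chains, aggregate)
  if (any(selected < 1L | selected > ncol(vfm$signal)))
    stop("selected indices out of range for this variant")
  if (length(selected) == 0L)
    warning("empty selection; using demographics-only inputs")
  X <- cbind(as.matrix(vfm$demo),
             vfm$signal[, selected, drop = FALSE])
  list(X = X, y = vfm$y, knee_id = vfm$knee_id)
}

#' Experiment configuration
#'
#' Bundles all stage configurations of the end-to-end pipeline, the
#' variant-to-chain mapping and the global seed. The Roman-numeral variant
#' names are labels only; each maps explicitly to its chain(s).
#'
#' @param sim A [vag_sim_config()].
#' @param emd An [emd_config()] (or `NULL` to skip EEMD cleaning).
#' @param nca An [nca_config()].
#' @param grid Candidate [network_spec()] list for the automatic search.
#' @param variant_chains Named list mapping variant labels to chains.
#' @param aggregate Channel aggregation, `"mean"` or `"channel"`.
#' @param tune_lambda Tune the NCA regularisation by CV (`FALSE` uses
#'   `1/N`).
#' @param min_slope,pad Segmentation controls.
#' @param threshold Decision cutoff for the confusion reports.
#' @param out_dir Output directory for report CSVs (`NULL`: in-memory
#'   only).
#' @param seed Global seed for splitting and training.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = vag_sim_config(), emd = emd_config(),
                              nca = nca_config(),
                              grid = default_network_grid(),
                              variant_chains = list(I = "CKC", II = "OKC",
                                                    III = c("CKC", "OKC")),
                              aggregate = "mean", tune_lambda = TRUE,
                              min_slope = 5, pad = 0.1, threshold = 0.5,
                              out_dir = NULL, seed = 1L) {
  cfg <- list(sim = sim, emd = emd, nca = nca, grid = grid,
              variant_chains = variant_chains, aggregate = aggregate,
              tune_lambda = tune_lambda, min_slope = min_slope, pad = pad,
              threshold = threshold, out_dir = out_dir,
              seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  if (cfg$sim$n_cycles < 1L) stop("config error: n_cycles must be >= 1")
  if (cfg$sim$n_hc + cfg$sim$n_oa == 0L)
    stop("config error: empty cohort")
  if (length(cfg$grid) == 0L) stop("config error: empty network grid")
  if (!all(unlist(cfg$variant_chains) %in% c("OKC", "CKC")))
    stop("config error: unknown chain in variant mapping")
  invisible(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full experiment: simulate, preprocess, select, classify,
#' evaluate
#'
#' Executes the pipeline for every configured variant: cohort simulation,
#' encoder-driven segmentation with EEMD trend removal, state-indicator
#' extraction, per-variant NCA feature selection, automatic MLP/RBF
#' architecture search on a stratified 70/15/15 split, and confusion/ROC
#' evaluation on all three partitions. Fully reproducible from the
#' configuration seeds. When `out_dir` is set, writes the feature table,
#' per-variant weight reports, network-quality summaries, confusion and ROC
#' CSVs, plus a provenance JSON.
#'
#' @param config An [experiment_config()].
#' @return A report bundle: list with `feature_table`, `variants` (each
#'   holding `nca`, `search`, `evaluations`) and `config`, invisibly
#'   classed `experiment_report`.
#' @export
run_experiment <- function(config = experiment_config()) {
  validate_experiment_config(config)
  dataset <- stage("simulate", generate_dataset(config$sim))
  ft <- stage("features",
              build_feature_table(dataset, config$emd,
                                  min_slope = config$min_slope,
                                  pad = config$pad))
  if (nrow(ft) == 0L) stop("stage features: empty feature table")
  variants <- list()
  for (v in names(config$variant_chains)) {
    chains <- config$variant_chains[[v]]
    vfm <- stage(paste0("variant ", v, " assemble"),
                 variant_feature_matrix(ft, chains, config$aggregate))
    sel <- stage(paste0("variant ", v, " nca"),
                 run_nca_selection(vfm$signal, vfm$y, config$nca,
                                   tune = config$tune_lambda))
    X <- cbind(as.matrix(vfm$demo),
               vfm$signal[, sel$selected, drop = FALSE])
    search <- stage(paste0("variant ", v, " train"),
                    auto_search(X, vfm$y, config$grid, seed = config$seed))
    evaluations <- list()
    for (kind in names(search$best)) {
      clf <- search$best[[kind]]
      evaluations[[kind]] <- lapply(
        list(train = search$split$train, test = search$split$test,
             validation = search$split$validation),
        function(idx) evaluate_classifier(clf, X[idx, , drop = FALSE],
                                          vfm$y[idx], config$threshold))
    }
    variants[[v]] <- list(chains = chains, nca = sel, search = search,
                          evaluations = evaluations,
                          n_inputs = ncol(X))
  }
  bundle <- structure(list(feature_table = ft, variants = variants,
                           config = config), class = "experiment_report")
  if (!is.null(config$out_dir)) write_experiment_outputs(bundle)
  invisible(bundle)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  for (v in names(x$variants)) {
    var <- x$variants[[v]]
    cat(sprintf("  variant %s (%s): %d measures selected\n", v,
                paste(var$chains, collapse = "+"), length(var$nca$selected)))
    for (kind in names(var$evaluations)) {
      ev <- var$evaluations[[kind]]$test
      cat(sprintf("    %-12s test accuracy %.2f%%  AUROC %.3f\n",
                  var$search$best[[kind]]$name,
                  ev$report$overall_accuracy, ev$auroc))
    }
  }
  invisible(x)
}

write_experiment_outputs <- function(bundle) {
  out <- bundle$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(bundle$feature_table, file.path(out, "features.csv"))
  summaries <- list(); confusion <- list(); rocs <- list()
  for (v in names(bundle$variants)) {
    var <- bundle$variants[[v]]
    write_nca_report(var$nca,
                     file.path(out, sprintf("nca_weights_variant_%s.csv", v)))
    s <- var$search$summary
    s <- cbind(variant = v, s)
    summaries[[v]] <- s
    for (kind in names(var$evaluations)) {
      for (part in names(var$evaluations[[kind]])) {
        ev <- var$evaluations[[kind]][[part]]
        cc <- cbind(variant = v,
                    network_name = var$search$best[[kind]]$name,
                    partition = part, ev$report$counts)
        confusion[[paste(v, kind, part)]] <- cc
        rc <- cbind(variant = v,
                    network_name = var$search$best[[kind]]$name,
                    partition = part, ev$roc,
                    auroc = ev$auroc, roc_threshold = ev$roc_threshold)
        rocs[[paste(v, kind, part)]] <- rc
      }
    }
  }
  write.csv(do.call(rbind, summaries),
            file.path(out, "network_quality.csv"), row.names = FALSE)
  write.csv(do.call(rbind, confusion),
            file.path(out, "classification_accuracy.csv"), row.names = FALSE)
  write.csv(do.call(rbind, rocs), file.path(out, "roc_curves.csv"),
            row.names = FALSE)
  cfg_json <- file.path(out, "provenance.json")
  cfg <- bundle$config
  cfg$grid <- lapply(cfg$grid, unclass)
  jsonlite::write_json(
    list(package = "vagdx",
         version = as.character(utils::packageVersion("vagdx")),
         config = lapply(unclass(cfg), function(x)
           if (is.list(x)) unclass(x) else x)),
    cfg_json, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}
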