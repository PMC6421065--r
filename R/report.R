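#' Experiment configuration
#'
#' Declares the factorial simulation study: generating conditions (tree
#' model x clock preset x taxon count x alignment length x replicates), the
#' inference grid (tree-prior label x clock mode), the root seed and the
#' output directory. The default mirrors the study's main grid: Yule and
#' birth-death generating trees (crown age 5, relative extinction 0.5 for
#' birth-death, generating rates fixed from the tip-count expectation), a
#' strict clock and the low-heterogeneity UCLN clock, 25 and 100 taxa,
#' 5000 bp, 10 replicate trees per condition, and all four
#' prior-label x clock-mode inference combinations per dataset.
#'
#' @param conditions Data frame with columns `tree_model` (`"yule"`/`"bd"`),
#'   `clock` (`"strict"`, `"low"`, `"medium"`, `"high"`), `n`, `L`, `n_rep`.
#' @param crown_age Crown age of all simulated trees (time units).
#' @param epsilon Relative extinction rate for birth-death conditions.
#' @param prior_modes,clock_modes Inference grid factors.
#' @param topology_source `"estimate"` or `"true"`.
#' @param smoothing Penalty weight for relaxed dating.
#' @param seed Root seed; every replicate's seed derives from it via
#'   [derive_seed()].
#' @param outdir Output directory for artifacts, or `NULL` for none.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(conditions = default_conditions(),
                              crown_age = 5, epsilon = 0.5,
                              prior_modes = c("yule", "bd"),
                              clock_modes = c("strict", "relaxed"),
                              topology_source = "estimate",
                              smoothing = 1, seed = 1, outdir = NULL) {
  conditions <- tibble::as_tibble(conditions)
  needed <- c("tree_model", "clock", "n", "L", "n_rep")
  if (!all(needed %in% names(conditions)))
    stop("`conditions` needs columns ", paste(needed, collapse = ", "))
  stopifnot(all(conditions$tree_model %in% c("yule", "bd")),
            all(conditions$clock %in% c("strict", "low", "medium", "high")),
            all(conditions$n_rep >= 1), all(conditions$n >= 3),
            all(conditions$L >= 1), crown_age > 0,
            epsilon >= 0, epsilon < 1, smoothing >= 0)
  structure(list(conditions = conditions, crown_age = crown_age,
                 epsilon = epsilon, prior_modes = prior_modes,
                 clock_modes = clock_modes,
                 topology_source = topology_source,
                 smoothing = smoothing, seed = as.integer(seed),
                 outdir = outdir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
default_conditions <- function() {
  tidyr::crossing(tree_model = c("yule", "bd"),
                  clock = c("strict", "low"),
                  n = c(25, 100)) |>
    dplyr::mutate(L = 5000, n_rep = 10)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment: ", nrow(x$conditions), " generating conditions x ",
      length(x$prior_modes) * length(x$clock_modes),
      " inference combinations (seed ", x$seed, ")\n", sep = "")
  print(x$conditions)
  invisible(x)
}

#' Read and write experiment configurations as YAML
#'
#' The file representation is a flat, human-editable YAML document;
#' configurations round-trip losslessly.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `read_experiment_config()` returns an `experiment_config`;
#'   the writer returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$conditions <- lapply(seq_len(nrow(config$conditions)),
                         function(i) as.list(config$conditions[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  conditions <- dplyr::bind_rows(lapply(x$conditions, tibble::as_tibble))
  experiment_config(conditions = conditions, crown_age = x$crown_age,
                    epsilon = x$epsilon, prior_modes = x$prior_modes,
                    clock_modes = x$clock_modes,
                    topology_source = x$topology_source,
                    smoothing = x$smoothing, seed = x$seed,
                    outdir = x$outdir)
}

#' Lineage-through-time curve of a chronogram
#'
#' The step function counting reconstructed lineages against time since the
#' root, computed from the branching times: it starts at 2 lineages at the
#' root and ends at `n`.
#'
#' @param phy A chronogram.
#' @return A tibble of class `ltt_curve` with columns `time` (since the
#'   root, ascending, length `n - 1`) and `lineages` (2, 3, ..., n).
#' @export
#' @examples
#' ltt_curve(simulate_chronogram(yule_params(1), 10, 5, seed = 1))
ltt_curve <- function(phy) {
  bt <- branching_times(phy)
  out <- tibble::tibble(time = max(bt) - bt, lineages = 2:(length(bt) + 1L))
  class(out) <- c("ltt_curve", class(out))
  out
}

#' Plot lineage-through-time curves
#'
#' Overlays LTT step curves (original versus estimated trees, or any named
#' set) on a natural-log-transformed lineage-count axis.
#'
#' @param ... Named chronograms or `ltt_curve` tibbles.
#' @return A ggplot object.
#' @export
plot_ltt <- function(...) {
  curves <- list(...)
  if (length(curves) == 1L && is.list(curves[[1]]) &&
      !inherits(curves[[1]], c("phylo", "ltt_curve")))
    curves <- curves[[1]]
  if (is.null(names(curves)) || any(names(curves) == ""))
    names(curves) <- paste0("tree", seq_along(curves))
  df <- dplyr::bind_rows(lapply(curves, function(x) {
    if (inherits(x, "phylo")) x <- ltt_curve(x)
    x
  }), .id = "tree")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, log(.data$lineages),
                                   colour = .data$tree)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time since root", y = "ln(lineages)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ltt
#' @param object An `ltt_curve`.
#' @export
autoplot.ltt_curve <- function(object, ...) {
  plot_ltt(ltt = object)
}

condition_clock <- function(clock) {
  if (clock == "strict") strict_clock() else ucln_preset(clock)
}

condition_model <- function(tree_model, n, crown_age, epsilon) {
  r <- expected_net_diversification(n, 2, crown_age)
  if (tree_model == "yule") yule_params(r) else bd_params(r, epsilon)
}

div_row <- function(bt, conditioning = "ntaxa") {
  fit_bd <- bd_mle(bt, conditioning)
  fit_yule <- yule_mle(bt, conditioning)
  tibble::tibble(r_hat = fit_bd$r_hat, eps_hat = fit_bd$eps_hat,
                 lambda_bd_hat = fit_bd$lambda_hat,
                 lambda_yule_hat = fit_yule$lambda_hat,
                 bd_loglik = fit_bd$loglik, yule_loglik = fit_yule$loglik,
                 bd_converged = fit_bd$converged,
                 yule_converged = fit_yule$converged)
}

#' Run the simulation experiment
#'
#' For every generating condition and replicate: simulate a chronogram,
#' draw branch rates, simulate an alignment; then for each inference
#' combination estimate a dated tree (the deterministic surrogate in
#' [infer_dated_tree()]), rescale it to the true crown age, and fit
#' birth-death and Yule models to its branching times. Diversification
#' fits on the original simulated trees are always included as the
#' reference. Because the tree-prior label does not enter the surrogate's
#' objective, each clock mode is estimated once per dataset and the result
#' is recorded under both prior labels.
#'
#' Everything is reproducible from the root seed; per-replicate seeds come
#' from [derive_seed()]. Stage failures are caught, recorded, and do not
#' stop the run.
#'
#' @param config An [experiment_config()].
#' @param stage How far to run: `"simulate"` (trees, rates, alignments
#'   only), `"infer"` (plus dated trees), `"estimate"` (plus
#'   diversification fits; default), `"report"` (plus summary tables and
#'   LTT plot files, written when `outdir` is set).
#' @param progress Print a line per replicate.
#' @return A list of class `experiment_result`: `replicates` (long tibble,
#'   one row per replicate x estimator), `summary` (comparison table from
#'   [summarize_experiment()]), `failures` (tibble of caught errors),
#'   `trees`, `dated` (lists of `phylo`, for LTT plotting), and `config`.
#' @export
run_experiment <- function(config, stage = c("estimate", "simulate", "infer",
                                             "report"),
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- match.arg(stage)
  stage_rank <- match(stage, c("simulate", "infer", "estimate", "report"))
  gtr <- gtr_params()
  rows <- list(); fails <- list(); trees <- list(); dated_trees <- list()
  counter <- 0L
  for (ci in seq_len(nrow(config$conditions))) {
    cond <- config$conditions[ci, ]
    model <- condition_model(cond$tree_model, cond$n, config$crown_age,
                             config$epsilon)
    clock <- condition_clock(cond$clock)
    for (rep_i in seq_len(cond$n_rep)) {
      counter <- counter + 1L
      seed <- derive_seed(config$seed, counter)
      label <- sprintf("%s_%s_n%d_L%d_rep%d", cond$tree_model, cond$clock,
                       cond$n, cond$L, rep_i)
      if (progress) message(label)
      res <- tryCatch({
        set.seed(seed)
        phy <- simulate_chronogram(model, cond$n, config$crown_age)
        rates <- draw_branch_rates(phy, clock)
        phylogram <- apply_rates(phy, rates)
        aln <- simulate_alignment(phylogram, gtr, cond$L)
        trees[[label]] <- phy
        out <- list()
        if (stage_rank >= 3L) {
          orig <- div_row(branching_times(phy))
          out$original <- dplyr::bind_cols(
            tibble::tibble(estimator = "original", prior_mode = NA_character_,
                           clock_mode = NA_character_), orig)
        }
        if (stage_rank >= 2L) {
          cfg <- inference_config(
            topology_source = config$topology_source,
            smoothing = config$smoothing,
            true_topology = if (config$topology_source == "true") phy)
          fits <- infer_dated_trees(aln, gtr, cfg, config$crown_age,
                                    clock_modes = config$clock_modes)
          for (cm in config$clock_modes) {
            fit <- fits[[cm]]
            dated_trees[[paste(label, cm, sep = "_")]] <- fit$chronogram
            if (stage_rank >= 3L) {
              est <- div_row(branching_times(fit$chronogram))
              for (pm in config$prior_modes) {
                out[[paste(pm, cm, sep = ":")]] <- dplyr::bind_cols(
                  tibble::tibble(estimator = paste(pm, cm, sep = ":"),
                                 prior_mode = pm, clock_mode = cm), est)
              }
            }
          }
        }
        if (length(out) > 0) {
          dplyr::bind_rows(out) |>
            dplyr::mutate(tree_model = cond$tree_model, clock = cond$clock,
                          n = cond$n, L = cond$L, replicate = rep_i,
                          seed = seed,
                          r_true = model$r, lambda_true = model$lambda,
                          .before = 1)
        } else NULL
      }, error = function(e) {
        fails[[label]] <<- tibble::tibble(replicate_label = label,
                                          error = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[label]] <- res
    }
  }
  replicates <- dplyr::bind_rows(rows)
  result <- structure(
    list(replicates = replicates,
         summary = if (nrow(replicates) > 0) summarize_experiment(replicates),
         failures = dplyr::bind_rows(fails),
         trees = trees, dated = dated_trees, config = config),
    class = "experiment_result")
  if (!is.null(config$outdir) && stage_rank >= 1L)
    write_experiment_artifacts(result, stage_rank)
  result
}

#' Summarize replicate estimates into a comparison table
#'
#' Medians and quartiles of the net-diversification and speciation-rate
#' estimates per generating condition and estimator; the `"original"`
#' estimator row (fits to the true simulated trees) is the reference
#' distribution.
#'
#' @param replicates The `replicates` tibble of an [run_experiment()]
#'   result (requires at least one completed replicate).
#' @return A tibble with one row per condition x estimator.
#' @export
summarize_experiment <- function(replicates) {
  if (is.null(replicates) || nrow(replicates) == 0)
    stop("no completed replicates to summarize")
  replicates |>
    dplyr::group_by(.data$tree_model, .data$clock, .data$n, .data$L,
                    .data$estimator) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      r_true = .data$r_true[1], lambda_true = .data$lambda_true[1],
      r_hat_median = median(.data$r_hat),
      r_hat_q25 = quantile(.data$r_hat, 0.25),
      r_hat_q75 = quantile(.data$r_hat, 0.75),
      lambda_yule_median = median(.data$lambda_yule_hat),
      lambda_yule_q25 = quantile(.data$lambda_yule_hat, 0.25),
      lambda_yule_q75 = quantile(.data$lambda_yule_hat, 0.75),
      .groups = "drop")
}

write_experiment_artifacts <- function(result, stage_rank) {
  config <- result$config
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (length(result$trees) > 0) {
    tr <- result$trees; class(tr) <- "multiPhylo"
    write_chronograms(tr, file.path(config$outdir, "original_trees.nwk"))
  }
  if (length(result$dated) > 0) {
    tr <- result$dated; class(tr) <- "multiPhylo"
    write_chronograms(tr, file.path(config$outdir, "estimated_trees.nwk"))
  }
  if (nrow(result$replicates %||% tibble::tibble()) > 0)
    write.csv(result$replicates,
              file.path(config$outdir, "replicates.csv"), row.names = FALSE)
  if (!is.null(result$summary))
    write.csv(result$summary,
              file.path(config$outdir, "comparison_table.csv"),
              row.names = FALSE)
  if (nrow(result$failures) > 0)
    write.csv(result$failures, file.path(config$outdir, "failures.csv"),
              row.names = FALSE)
  if (stage_rank >= 4L && length(result$dated) > 0) {
    for (lab in names(result$trees)) {
      est <- result$dated[grep(paste0("^", lab, "_"), names(result$dated))]
      if (length(est) == 0) next
      p <- plot_ltt(c(list(original = result$trees[[lab]]), est))
      ggplot2::ggsave(file.path(config$outdir, paste0("ltt_", lab, ".pdf")),
                      p, width = 6, height = 4)
    }
  }
  invisible(result)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment result: ", nrow(x$replicates), " estimate rows, ",
      nrow(x$failures), " failures\n", sep = "")
  if (!is.null(x$summary)) print(x$summary, n = 20)
  invisible(x)
}
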