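#' False discovery curve from a ranking against simulation truth
#'
#' Given genes ordered from most to least significant, counts how many
#' truly-null genes appear among the top r for every rank r. When
#' `restrict_common` is set, genes expressed uniquely in one condition are
#' dropped from the ranking before counting, so the curve reflects errors
#' among the genes that are actually comparable between conditions.
#'
#' @param ranking character vector of gene identifiers, most significant
#'   first (for example `de$gene[order(de$p_value)]`).
#' @param experiment a [simulate_experiment()] result providing the truth,
#'   or a truth data frame with columns `gene`, `is_de` and `unique_to` (as
#'   written by the `simulate` CLI subcommand).
#' @param restrict_common drop condition-unique genes from the ranking
#'   (default `TRUE`).
#' @param max_rank optional truncation of the curve.
#' @return A data frame of class `"fd_curve"` with columns `rank` and
#'   `false_discoveries` (cumulative truly-null genes among the top-ranked).
#' @export
false_discovery_curve <- function(ranking, experiment, restrict_common = TRUE,
                                  max_rank = NULL) {
  truth <- if (inherits(experiment, "sim_experiment")) experiment$truth
           else as.data.frame(experiment)
  need <- c("gene", "is_de", "unique_to")
  if (!all(need %in% names(truth)))
    stop("truth must provide columns: ", paste(need, collapse = ", "))
  truth$is_de <- as.logical(truth$is_de)
  truth$unique_to <- as.character(truth$unique_to)
  i <- match(ranking, truth$gene)
  if (anyNA(i))
    stop("unknown gene in ranking: '", ranking[which(is.na(i))[1L]], "'")
  if (restrict_common) i <- i[truth$unique_to[i] == "none"]
  fd <- cumsum(!truth$is_de[i])
  out <- data.frame(rank = seq_along(fd), false_discoveries = fd)
  if (!is.null(max_rank)) out <- out[out$rank <= max_rank, , drop = FALSE]
  class(out) <- c("fd_curve", "data.frame")
  out
}

#' Count significant genes by direction at an FDR threshold
#'
#' @param de a `"de_table"` (see e.g. [poisson_lr_test()]).
#' @param fdr_threshold call a gene significant when `fdr < fdr_threshold`;
#'   must lie in (0, 1\].
#' @return A list of class `"direction_summary"`: `n_up_1`, `n_up_2`
#'   (significant genes higher in group 1 / group 2), `prop_up_1`,
#'   `prop_up_2` (`NA` when nothing is significant), `fdr_threshold`.
#' @export
direction_summary <- function(de, fdr_threshold = 0.001) {
  stopifnot(inherits(de, "de_table"))
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
    stop("'fdr_threshold' must lie in (0, 1]")
  sig <- de$fdr < fdr_threshold
  n1 <- sum(sig & de$direction == "up")
  n2 <- sum(sig & de$direction == "down")
  tot <- n1 + n2
  structure(list(n_up_1 = n1, n_up_2 = n2,
                 prop_up_1 = if (tot > 0) n1 / tot else NA_real_,
                 prop_up_2 = if (tot > 0) n2 / tot else NA_real_,
                 fdr_threshold = fdr_threshold,
                 group_labels = attr(de, "group_labels")),
            class = "direction_summary")
}

#' @export
print.direction_summary <- function(x, ...) {
  gl <- x$group_labels
  cat("Significant genes at FDR < ", format(x$fdr_threshold), ":\n", sep = "")
  cat("  higher in ", gl[1L], ": ", x$n_up_1,
      if (!is.na(x$prop_up_1)) sprintf(" (%.0f%%)", 100 * x$prop_up_1),
      "\n", sep = "")
  cat("  higher in ", gl[2L], ": ", x$n_up_2,
      if (!is.na(x$prop_up_2)) sprintf(" (%.0f%%)", 100 * x$prop_up_2),
      "\n", sep = "")
  invisible(x)
}

#' Median log-ratio of a gene subset
#'
#' Summarizes where a designated gene set (typically housekeeping genes,
#' presumed non-differential) sits in the M-value distribution of a library
#' pair. A subset median clearly offset from zero, close to the estimated
#' log2 normalization factor, is the diagnostic signature of composition
#' bias that scaling to library size alone does not remove.
#'
#' @param ma an `"ma_stats"` object from [compute_ma()].
#' @param subset character vector of gene identifiers.
#' @param density also return a smoothed distribution of the subset M values
#'   (Gaussian kernel, Silverman's rule-of-thumb bandwidth) for overlay
#'   plots (default `TRUE`).
#' @return A list of class `"subset_offset"`: `median_M`, `n` (genes used),
#'   and when requested a `density` data frame (`x`, `y`) with the
#'   `bandwidth` used.
#' @export
subset_offset <- function(ma, subset, density = TRUE) {
  stopifnot(inherits(ma, "ma_stats"))
  m <- ma$M[ma$valid & ma$gene %in% subset]
  if (length(m) == 0L)
    stop("subset has no genes with valid M values in this pair")
  out <- list(median_M = stats::median(m), n = length(m))
  if (density && length(m) >= 2L) {
    d <- stats::density(m, bw = "nrd0", kernel = "gaussian")
    out$density <- data.frame(x = d$x, y = d$y)
    out$bandwidth <- d$bw
  }
  structure(out, class = "subset_offset")
}

#' @export
print.subset_offset <- function(x, ...) {
  cat(sprintf("subset of %d genes: median M = %.4f\n", x$n, x$median_M))
  invisible(x)
}

#' Factor-recovery sweep over simulation configurations
#'
#' Runs each configuration, estimates the TMM production ratio between the
#' first libraries of the two conditions, and compares it with the true
#' ratio of total RNA outputs — the simulation counterpart of checking
#' estimated factors against truth across a parameter grid.
#'
#' @param configs list of [sim_config()] objects.
#' @param params a [trim_params()] object for the estimator.
#' @return A data frame of class `"recovery_sweep"` with one row per run:
#'   `n_common`, `n_unique_1`, `n_unique_2`, `prop_de`, `seed`,
#'   `true_ratio` (S_1/S_2), `estimated_ratio` and `rel_error`; quantiles of
#'   the absolute relative error are attached as attribute
#'   `error_quantiles`.
#' @export
recovery_sweep <- function(configs, params = trim_params()) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L,
            all(vapply(configs, inherits, logical(1L), "sim_config")))
  rows <- lapply(configs, function(cfg) {
    ex <- simulate_experiment(cfg)
    lib1 <- names(ex$design)[ex$design == "1"][1L]
    lib2 <- names(ex$design)[ex$design == "2"][1L]
    fit <- tmm_pair(ex$counts, lib1, lib2, params)
    tr <- true_factor(ex, "1", "2")
    data.frame(n_common = cfg$n_common, n_unique_1 = cfg$n_unique_1,
               n_unique_2 = cfg$n_unique_2, prop_de = cfg$prop_de,
               seed = cfg$seed, true_ratio = tr,
               estimated_ratio = fit$production_ratio,
               rel_error = fit$production_ratio / tr - 1)
  })
  out <- do.call(rbind, rows)
  attr(out, "error_quantiles") <-
    stats::quantile(abs(out$rel_error), c(0.5, 0.9, 0.95, 1))
  class(out) <- c("recovery_sweep", "data.frame")
  out
}
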