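#' Gene-wise M and A statistics for a pair of libraries
#'
#' For each gene g with counts Y_gk, Y_gr and library sizes N_k, N_r:
#' \deqn{M_g = \log_2\frac{Y_{gk}/N_k}{Y_{gr}/N_r}, \qquad
#'       A_g = \tfrac12 \log_2\left(\frac{Y_{gk}}{N_k}\cdot\frac{Y_{gr}}{N_r}\right)}
#' with a delta-method approximation to the variance of M (the log relative
#' risk of a binomial proportion per library):
#' \deqn{\widehat{var}(M_g) = \frac{N_k - Y_{gk}}{N_k Y_{gk}} +
#'                            \frac{N_r - Y_{gr}}{N_r Y_{gr}}}
#' Genes with a zero count in either library have no defined log-ratio and
#' are flagged invalid (they are removed ahead of any trimming). M is
#' computed as a difference of log2 proportions so that swapping k and r
#' negates it exactly.
#'
#' @param x a [count_matrix()].
#' @param k,r library identifiers (k = sample, r = reference).
#' @return A data frame of class `"ma_stats"` with one row per gene:
#'   `gene`, `M`, `A`, `var_M`, `weight` (= 1/var_M) and `valid`. Library
#'   ids and sizes are carried in attributes `sample_id`, `reference_id`,
#'   `lib_sizes`.
#' @export
compute_ma <- function(x, k, r) {
  stopifnot(inherits(x, "count_matrix"))
  ik <- .lib_index(x, k)
  ir <- .lib_index(x, r)
  nk <- x$lib_sizes[[ik]]
  nr <- x$lib_sizes[[ir]]
  if (nk <= 0 || nr <= 0) stop("library sizes must be positive")
  yk <- x$counts[, ik]
  yr <- x$counts[, ir]
  valid <- yk > 0 & yr > 0
  M <- A <- var_M <- rep.int(NA_real_, length(yk))
  lk <- log2(yk[valid] / nk)
  lr <- log2(yr[valid] / nr)
  M[valid] <- lk - lr
  A[valid] <- (lk + lr) / 2
  var_M[valid] <- (nk - yk[valid]) / (nk * yk[valid]) +
                  (nr - yr[valid]) / (nr * yr[valid])
  # a gene holding an entire library in both samples has zero approximate
  # variance; its weight is undefined, so it cannot enter the weighted mean
  degen <- valid & var_M == 0
  if (any(degen, na.rm = TRUE)) {
    warning(sum(degen, na.rm = TRUE),
            " gene(s) with counts equal to both library sizes excluded",
            " (zero delta-method variance)")
    valid[which(degen)] <- FALSE
  }
  out <- data.frame(gene = gene_ids(x), M = M, A = A, var_M = var_M,
                    weight = 1 / var_M, valid = valid,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sample_id") <- k
  attr(out, "reference_id") <- r
  attr(out, "lib_sizes") <- c(sample = nk, reference = nr)
  class(out) <- c("ma_stats", "data.frame")
  out
}

#' Trimming parameters for the TMM estimator
#'
#' @param m_trim fraction in \[0, 0.5) removed from *each* tail of the
#'   M-value distribution (default 0.30).
#' @param a_trim fraction in \[0, 0.5) removed from *each* tail of the
#'   A-value distribution (default 0.05).
#' @param a_min optional lower bound on A; genes with A below it are dropped
#'   before trimming (useful for data sets with unstable low-abundance
#'   log-ratios).
#' @param weighted use precision weights 1/var(M) in the trimmed mean
#'   (default `TRUE`); `FALSE` gives the unweighted trimmed mean.
#' @return An object of class `"trim_params"`.
#' @export
trim_params <- function(m_trim = 0.30, a_trim = 0.05, a_min = NULL,
                        weighted = TRUE) {
  stopifnot(is.numeric(m_trim), length(m_trim) == 1L, m_trim >= 0, m_trim < 0.5,
            is.numeric(a_trim), length(a_trim) == 1L, a_trim >= 0, a_trim < 0.5,
            is.null(a_min) || (is.numeric(a_min) && length(a_min) == 1L),
            isTRUE(weighted) || isFALSE(weighted))
  structure(list(m_trim = m_trim, a_trim = a_trim, a_min = a_min,
                 weighted = weighted),
            class = "trim_params")
}

#' Doubly trim gene-wise M/A statistics
#'
#' Removes a fixed fraction from each tail of the M distribution and of the
#' A distribution over the same candidate pool, and returns the intersection
#' of the two keep-sets (the set G* entering the weighted mean). With n
#' candidate genes, each trim keeps ranks `floor(n*f)+1 .. n-floor(n*f)`
#' (1-based). Tied values share their average rank, so a tied group is kept
#' or removed as a whole; this makes the trim exactly mirror-symmetric under
#' swapping the two libraries (M negates), which keeps the estimator
#' antisymmetric even on heavily tied count data.
#'
#' @param ma an `"ma_stats"` object from [compute_ma()].
#' @param params a [trim_params()] object.
#' @return Character vector of kept gene identifiers.
#' @export
doubly_trim <- function(ma, params = trim_params()) {
  stopifnot(inherits(ma, "ma_stats"), inherits(params, "trim_params"))
  keep <- ma$valid
  if (!is.null(params$a_min)) keep <- keep & !is.na(ma$A) & ma$A >= params$a_min
  idx <- which(keep)
  n <- length(idx)
  if (n == 0L) stop("no valid genes to trim (all zero in one library",
                    if (!is.null(params$a_min)) " or below 'a_min'", ")")
  in_band <- function(v, frac) {
    lo <- floor(n * frac) + 1L
    hi <- n - floor(n * frac)
    rk <- rank(v, ties.method = "average")
    rk >= lo & rk <= hi
  }
  sel <- in_band(ma$M[idx], params$m_trim) & in_band(ma$A[idx], params$a_trim)
  if (!any(sel))
    stop("trimming removed every gene; use smaller 'm_trim'/'a_trim' fractions")
  ma$gene[idx[sel]]
}

#' Pairwise TMM normalization factor
#'
#' Estimates the scaling factor for library `k` against reference `r` as the
#' precision-weighted doubly trimmed mean of the gene-wise log-fold-changes:
#' \deqn{\log_2 f_{k} = \frac{\sum_{g \in G^*} w_g M_g}
#'                           {\sum_{g \in G^*} w_g}, \qquad w_g = 1/\widehat{var}(M_g)}
#' where G* is the trimmed gene set of [doubly_trim()]. The linear factor
#' \eqn{2^{\log_2 f_k}} multiplies library k's size to give its effective
#' size; its reciprocal estimates the relative total RNA output
#' \eqn{S_k/S_r} of the two samples (a library whose sample produces more
#' RNA gets a factor below 1, shrinking its effective size and raising its
#' normalized expression).
#'
#' @param x a [count_matrix()].
#' @param k,r library identifiers (sample and reference).
#' @param params a [trim_params()] object.
#' @return An object of class `"tmm_fit"`: list with `log2_factor`, `factor`,
#'   `production_ratio` (= 1/factor), `kept_genes`, `n_zero_removed`,
#'   `n_trimmed`, `sample_id`, `reference_id`, `params`, and the `ma` table.
#' @examples
#' m <- matrix(rpois(600, 50), ncol = 2,
#'             dimnames = list(paste0("g", 1:300), c("a", "b")))
#' fit <- tmm_pair(count_matrix(m), "a", "b")
#' fit$factor
#' @export
tmm_pair <- function(x, k, r, params = trim_params()) {
  ma <- compute_ma(x, k, r)
  kept <- doubly_trim(ma, params)
  i <- match(kept, ma$gene)
  m <- ma$M[i]
  w <- if (params$weighted) ma$weight[i] else rep.int(1, length(i))
  log2_factor <- sum(w * m) / sum(w)
  n_valid <- sum(ma$valid)
  structure(list(log2_factor = log2_factor,
                 factor = 2^log2_factor,
                 production_ratio = 2^(-log2_factor),
                 kept_genes = kept,
                 n_zero_removed = nrow(ma) - n_valid,
                 n_trimmed = n_valid - length(kept),
                 sample_id = k, reference_id = r,
                 params = params, ma = ma),
            class = "tmm_fit")
}

#' @export
print.tmm_fit <- function(x, ...) {
  cat("TMM fit: ", x$sample_id, " vs reference ", x$reference_id, "\n", sep = "")
  cat(sprintf("  factor            %.4f  (log2 %.4f)\n", x$factor, x$log2_factor))
  cat(sprintf("  production ratio  %.4f  (S_%s / S_%s)\n",
              x$production_ratio, x$sample_id, x$reference_id))
  cat("  genes: ", length(x$kept_genes), " kept, ", x$n_trimmed, " trimmed, ",
      x$n_zero_removed, " removed for zeros\n", sep = "")
  invisible(x)
}

#' Fit TMM normalization factors across libraries
#'
#' The main fitting function: selects a reference library and computes the
#' pairwise TMM factor of every other library against it. The reference
#' keeps factor 1; factors are not rescaled afterwards. Effective library
#' sizes are the observed sizes multiplied by the factors and are the
#' exposure (offset) the count-based tests consume.
#'
#' @param x a [count_matrix()] with at least two libraries.
#' @param reference a library identifier, or `"auto"` to pick the library
#'   whose median A value against the first library is closest to zero (a
#'   deterministic middle-of-the-road choice); the default is the first
#'   library.
#' @param m_trim,a_trim,a_min,weighted trimming parameters, see
#'   [trim_params()].
#' @return An object of class `"tmm"` with components `factors`,
#'   `log2_factors`, `effective_sizes` (named numeric vectors over
#'   libraries), `reference`, `fits` (per-library `"tmm_fit"` objects,
#'   `NULL` for the reference), `lib_sizes` and `call`. Methods: `print`,
#'   `summary`, `coef` (the factors), `plot` (MA plot against the
#'   reference).
#' @examples
#' m <- matrix(rpois(900, 60), ncol = 3,
#'             dimnames = list(paste0("g", 1:300), c("a", "b", "c")))
#' fit <- tmm(count_matrix(m))
#' coef(fit)
#' @export
tmm <- function(x, reference = library_ids(x)[1L], m_trim = 0.30,
                a_trim = 0.05, a_min = NULL, weighted = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  libs <- library_ids(x)
  if (length(libs) < 2L) stop("need at least two libraries")
  params <- trim_params(m_trim, a_trim, a_min, weighted)
  if (identical(reference, "auto")) {
    med_a <- vapply(libs, function(l) {
      if (l == libs[1L]) return(0)
      ma <- compute_ma(x, l, libs[1L])
      stats::median(ma$A[ma$valid])
    }, numeric(1L))
    # library whose abundance profile sits closest to the first library's
    reference <- libs[which.min(abs(med_a))]
  }
  if (!reference %in% libs) stop("unknown reference library: '", reference, "'")
  fits <- stats::setNames(vector("list", length(libs)), libs)
  log2f <- stats::setNames(numeric(length(libs)), libs)
  for (l in libs) {
    if (l == reference) next
    fits[[l]] <- tryCatch(tmm_pair(x, l, reference, params),
                          error = function(e)
                            stop("TMM failed for pair (", l, ", ", reference,
                                 "): ", conditionMessage(e), call. = FALSE))
    log2f[[l]] <- fits[[l]]$log2_factor
  }
  factors <- 2^log2f
  structure(list(factors = factors,
                 log2_factors = log2f,
                 effective_sizes = x$lib_sizes * factors,
                 lib_sizes = x$lib_sizes,
                 reference = reference,
                 fits = fits,
                 params = params,
                 call = match.call()),
            class = "tmm")
}

#' @export
print.tmm <- function(x, digits = 4L, ...) {
  cat("TMM normalization (reference: ", x$reference, ")\n", sep = "")
  print(round(x$factors, digits))
  invisible(x)
}

#' @export
coef.tmm <- function(object, ...) object$factors

#' @export
summary.tmm <- function(object, ...) {
  libs <- names(object$factors)
  df <- data.frame(
    library = libs,
    factor = unname(object$factors),
    log2_factor = unname(object$log2_factors),
    lib_size = unname(object$lib_sizes),
    effective_size = unname(object$effective_sizes),
    n_kept = vapply(libs, function(l)
      if (is.null(object$fits[[l]])) NA_integer_
      else length(object$fits[[l]]$kept_genes), integer(1L)),
    n_trimmed = vapply(libs, function(l)
      if (is.null(object$fits[[l]])) NA_integer_
      else object$fits[[l]]$n_trimmed, integer(1L)),
    n_zero_removed = vapply(libs, function(l)
      if (is.null(object$fits[[l]])) NA_integer_
      else object$fits[[l]]$n_zero_removed, integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("summary.tmm", "data.frame")
  attr(df, "reference") <- object$reference
  df
}

#' @export
print.summary.tmm <- function(x, ...) {
  cat("TMM normalization factors (reference: ", attr(x, "reference"), ")\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5L)
  invisible(x)
}

#' MA plot of a fitted library against the reference
#'
#' @param x a `"tmm"` object.
#' @param library which non-reference library to plot (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.tmm <- function(x, library = NULL, ...) {
  cand <- setdiff(names(x$factors), x$reference)
  if (is.null(library)) library <- cand[1L]
  fit <- x$fits[[library]]
  if (is.null(fit)) stop("no fit stored for library '", library, "'")
  ma <- fit$ma
  ok <- ma$valid
  kept <- ma$gene %in% fit$kept_genes
  graphics::plot(ma$A[ok], ma$M[ok], pch = 16, cex = 0.4,
                 col = ifelse(kept[ok], "black", "grey70"),
                 xlab = "A (average log2 abundance)",
                 ylab = paste0("M (log2 ", library, " / ", x$reference, ")"),
                 ...)
  graphics::abline(h = 0, col = "grey50", lty = 2)
  graphics::abline(h = fit$log2_factor, col = "red")
  invisible(x)
}

#' Effective library sizes for a two-library comparison
#'
#' Splits the factor symmetrically: the sample library size is multiplied by
#' the square root of the factor and the reference size divided by it, so
#' that the ratio of the adjusted sizes is `(n_k/n_r) * factor` while their
#' product is preserved.
#'
#' @param n_k,n_r observed library sizes (sample, reference).
#' @param factor the TMM factor of the sample library against the reference.
#' @return Numeric vector `c(n_k * sqrt(factor), n_r / sqrt(factor))`.
#' @export
effective_sizes_two_sample <- function(n_k, n_r, factor) {
  stopifnot(is.numeric(n_k), is.numeric(n_r), is.numeric(factor),
            n_k > 0, n_r > 0, factor > 0)
  c(n_k * sqrt(factor), n_r / sqrt(factor))
}
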