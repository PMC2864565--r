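#' Conditional exact binomial test for two count libraries
#'
#' Tests, gene by gene, whether a count pair (y1, y2) is consistent with the
#' two libraries sampling the gene at the same underlying rate, given their
#' (effective) sizes n1 and n2. Conditional on the total t = y1 + y2,
#' y1 ~ Binomial(t, n1/(n1+n2)) under the null; the two-sided p-value sums
#' the probabilities of all outcomes no more likely than the observed one
#' (minimum-likelihood two-sided convention, with a relative slack of 1e-7
#' for floating-point ties). A pair with t = 0 carries no information and
#' returns p = 1.
#'
#' For totals up to 10,000 the conditional pmf is summed directly; for
#' larger totals the same p-value is assembled from two binomial tail
#' probabilities, locating the opposite-tail cutoff by binary search on the
#' monotone flank of the unimodal pmf.
#'
#' @param y1,y2 non-negative integer count vectors (recycled to a common
#'   length).
#' @param n1,n2 positive (effective) library sizes, scalars or vectors.
#' @return Numeric vector of p-values in \[0, 1\].
#' @examples
#' exact_binomial_test(5, 0, 1e6, 1e6)   # 2 * 0.5^5 = 0.0625
#' @export
exact_binomial_test <- function(y1, y2, n1, n2) {
  k <- max(length(y1), length(y2), length(n1), length(n2))
  y1 <- rep_len(as.numeric(y1), k); y2 <- rep_len(as.numeric(y2), k)
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  if (any(y1 < 0 | y2 < 0)) stop("counts must be non-negative")
  if (any(y1 != floor(y1) | y2 != floor(y2))) stop("counts must be whole numbers")
  if (any(n1 <= 0 | n2 <= 0)) stop("library sizes must be positive")
  pr <- n1 / (n1 + n2)
  t <- y1 + y2
  vapply(seq_len(k), function(i) .binom_two_sided(y1[i], t[i], pr[i]),
         numeric(1L))
}

# two-sided minimum-likelihood binomial p-value
.binom_two_sided <- function(y, t, pr, slack = 1 + 1e-7) {
  if (t == 0) return(1)
  d_obs <- stats::dbinom(y, t, pr) * slack
  if (t <= 10000) {
    d <- stats::dbinom(0:t, t, pr)
    qual <- d <= d_obs
    if (all(qual)) return(1)   # observed at the mode: exact p is 1
    return(min(1, sum(d[qual])))
  }
  mode <- floor((t + 1) * pr)
  if (y <= mode) {
    p <- stats::pbinom(y, t, pr)
    # smallest x in (mode, t] with pmf <= observed pmf, if any
    if (stats::dbinom(t, t, pr) <= d_obs) {
      lo <- max(mode, y) + 1; hi <- t
      if (lo <= hi && stats::dbinom(lo, t, pr) > d_obs) {
        while (hi - lo > 1) {
          mid <- floor((lo + hi) / 2)
          if (stats::dbinom(mid, t, pr) <= d_obs) hi <- mid else lo <- mid
        }
        lo <- hi
      }
      if (lo <= t) p <- p + stats::pbinom(lo - 1, t, pr, lower.tail = FALSE)
    }
  } else {
    p <- stats::pbinom(y - 1, t, pr, lower.tail = FALSE)
    if (stats::dbinom(0, t, pr) <= d_obs) {
      lo <- 0; hi <- min(mode, y - 1)
      if (hi >= 0 && stats::dbinom(hi, t, pr) > d_obs) {
        while (hi - lo > 1) {
          mid <- floor((lo + hi) / 2)
          if (stats::dbinom(mid, t, pr) <= d_obs) lo <- mid else hi <- mid
        }
        hi <- lo
      }
      if (hi >= 0) p <- p + stats::pbinom(hi, t, pr)
    }
  }
  min(1, p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# assemble the common DETable layout; log2 fold changes use normalized
# proportions with a half-count continuity offset only when a zero is
# involved (display only -- the p-values are exact and uncorrected)
.de_table <- function(genes, y1, y2, n1, n2, p, statistic,
                      group_labels = c("1", "2")) {
  cont <- ifelse(y1 == 0 | y2 == 0, 0.5, 0)
  lfc <- log2(((y1 + cont) / n1) / ((y2 + cont) / n2))
  direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none"))
  out <- data.frame(gene = genes, log2_fc = lfc, statistic = statistic,
                    p_value = p, fdr = bh_adjust(p), direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "group_labels") <- group_labels
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, n = 10L, ...) {
  gl <- attr(x, "group_labels")
  cat("Differential expression table: ", nrow(x), " genes (",
      gl[1L], " vs ", gl[2L], ")\n", sep = "")
  ord <- order(x$p_value)
  print.data.frame(utils::head(x[ord, ], n), row.names = FALSE, digits = 4L)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more, sorted by p-value)\n", sep = "")
  invisible(x)
}

#' Exact test between two libraries
#'
#' Applies [exact_binomial_test()] to every gene of a pair of libraries.
#' With a TMM fit supplied, the observed library sizes are replaced by the
#' two-sample effective sizes (square-root split of the factor, see
#' [effective_sizes_two_sample()]); otherwise raw sizes are used.
#'
#' @param x a [count_matrix()].
#' @param k,r library identifiers (sample, reference).
#' @param norm optional `"tmm_fit"` from [tmm_pair()] (its orientation must
#'   match: sample `k`, reference `r`), or a bare numeric factor.
#' @return A `"de_table"` data frame: `gene`, `log2_fc` (k vs r), `statistic`
#'   (the count in k), `p_value`, `fdr`, `direction`.
#' @export
two_library_test <- function(x, k, r, norm = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  ik <- .lib_index(x, k); ir <- .lib_index(x, r)
  nk <- x$lib_sizes[[ik]]; nr <- x$lib_sizes[[ir]]
  if (!is.null(norm)) {
    f <- if (inherits(norm, "tmm_fit")) {
      if (!identical(norm$sample_id, k) || !identical(norm$reference_id, r))
        stop("normalization fit orientation (", norm$sample_id, " vs ",
             norm$reference_id, ") does not match the requested pair")
      norm$factor
    } else as.numeric(norm)
    eff <- effective_sizes_two_sample(nk, nr, f)
    nk <- eff[1L]; nr <- eff[2L]
  }
  y1 <- x$counts[, ik]; y2 <- x$counts[, ir]
  p <- exact_binomial_test(y1, y2, nk, nr)
  .de_table(gene_ids(x), y1, y2, nk, nr, p, statistic = y1,
            group_labels = c(k, r))
}

#' Two-group design with effective library sizes
#'
#' Maps each library to one of two condition labels and carries the
#' per-library effective size used as the model offset/exposure. Effective
#' sizes are typically `effective_sizes` from a fitted [tmm()] object
#' (library size times TMM factor), or the raw sizes for library-size-only
#' normalization.
#'
#' @param groups named character (or factor) vector: library id -> group
#'   label; exactly two distinct labels.
#' @param eff_sizes named numeric vector of positive effective sizes over
#'   the same libraries.
#' @return An object of class `"group_design"`.
#' @export
group_design <- function(groups, eff_sizes) {
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be named by library id")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two distinct group labels, got ",
                              length(lev))
  if (!all(names(groups) %in% names(eff_sizes)))
    stop("every library in 'groups' needs an effective size")
  eff_sizes <- eff_sizes[names(groups)]
  if (anyNA(eff_sizes) || any(eff_sizes <= 0))
    stop("effective sizes must be positive")
  structure(list(groups = groups, eff_sizes = eff_sizes, levels = lev),
            class = "group_design")
}

#' Poisson likelihood-ratio test for two groups of libraries
#'
#' Per gene, counts are modelled as Y_gk ~ Poisson(lambda_{g,z(k)} * n_k)
#' with n_k the effective library size of library k (the normalization
#' enters through this offset). The group and pooled rate MLEs are closed
#' form (group count sums over group effective-size sums), giving the LR
#' statistic
#' \deqn{LR_g = 2 \sum_k Y_{gk}\,\ln\frac{\hat\lambda_{z(k)}}{\hat\lambda_0}}
#' (terms with Y = 0 contribute 0) referred to a chi-squared distribution
#' with one degree of freedom.
#'
#' @param x a [count_matrix()].
#' @param design a [group_design()].
#' @return A `"de_table"`; `statistic` is the LR statistic, `log2_fc` the
#'   normalized group-1 vs group-2 fold change.
#' @export
poisson_lr_test <- function(x, design) {
  stopifnot(inherits(x, "count_matrix"), inherits(design, "group_design"))
  libs <- names(design$groups)
  miss <- setdiff(libs, library_ids(x))
  if (length(miss)) stop("unknown library id: '", miss[1L], "'")
  y <- x$counts[, libs, drop = FALSE]
  g1 <- design$groups == design$levels[1L]
  n <- design$eff_sizes
  s1 <- rowSums(y[, g1, drop = FALSE]); s2 <- rowSums(y[, !g1, drop = FALSE])
  N1 <- sum(n[g1]); N2 <- sum(n[!g1])
  lam1 <- s1 / N1; lam2 <- s2 / N2; lam0 <- (s1 + s2) / (N1 + N2)
  term <- function(s, lam) ifelse(s > 0, s * log(lam / lam0), 0)
  lr <- pmax(0, 2 * (term(s1, lam1) + term(s2, lam2)))
  p <- stats::pchisq(lr, df = 1L, lower.tail = FALSE)
  p[s1 + s2 == 0] <- 1
  .de_table(gene_ids(x), s1, s2, N1, N2, p, statistic = lr,
            group_labels = design$levels)
}

#' Exact Poisson test for two groups of libraries
#'
#' Group totals of independent Poisson counts are Poisson, so conditioning
#' on the overall total reduces the two-group comparison to the binomial
#' situation of [exact_binomial_test()] with the summed effective sizes as
#' the exposure split: counts are pooled within each group and the exact
#' conditional test applied to the pooled pair. With one library per group
#' this is identical to [two_library_test()] on pre-adjusted sizes.
#'
#' @inheritParams poisson_lr_test
#' @return A `"de_table"`; `statistic` is the pooled group-1 count.
#' @export
poisson_exact_test <- function(x, design) {
  stopifnot(inherits(x, "count_matrix"), inherits(design, "group_design"))
  libs <- names(design$groups)
  miss <- setdiff(libs, library_ids(x))
  if (length(miss)) stop("unknown library id: '", miss[1L], "'")
  y <- x$counts[, libs, drop = FALSE]
  g1 <- design$groups == design$levels[1L]
  s1 <- rowSums(y[, g1, drop = FALSE]); s2 <- rowSums(y[, !g1, drop = FALSE])
  N1 <- sum(design$eff_sizes[g1]); N2 <- sum(design$eff_sizes[!g1])
  p <- exact_binomial_test(s1, s2, N1, N2)
  .de_table(gene_ids(x), s1, s2, N1, N2, p, statistic = s1,
            group_labels = design$levels)
}
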