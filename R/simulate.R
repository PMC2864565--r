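#' Expression-value sampler for the simulator
#'
#' Base per-gene expression values are drawn either from the empirical
#' distribution of observed counts in a user-supplied library (sampling the
#' positive counts with replacement) or from a heavy-tailed parametric
#' fallback: exp(Normal(log_mean, log_sd)) rounded up to at least 1. The
#' empirical route reproduces the skewed count structure of a real library;
#' the fallback approximates it without any external data.
#'
#' @param counts optional numeric vector of observed counts (for example one
#'   column of a [count_matrix()]); needs at least 100 positive values.
#' @param log_mean,log_sd natural-log-scale location and spread of the
#'   parametric fallback (defaults 4 and 2: median around 55 with a long
#'   right tail, a realistic shape for per-gene read counts).
#' @return A function `f(n)` returning `n` positive expression values.
#' @export
build_source <- function(counts = NULL, log_mean = 4, log_sd = 2) {
  if (!is.null(counts)) {
    pos <- counts[!is.na(counts) & counts > 0]
    if (length(pos) < 100L)
      stop("empirical source needs at least 100 positive counts, got ",
           length(pos))
    force(pos)
    return(function(n) sample(pos, n, replace = TRUE))
  }
  stopifnot(is.numeric(log_mean), is.numeric(log_sd), log_sd >= 0)
  function(n) pmax(ceiling(exp(stats::rnorm(n, log_mean, log_sd))), 1)
}

#' Simulation configuration
#'
#' Describes a two-condition RNA-seq experiment with controlled RNA
#' composition differences: genes expressed in both conditions, genes unique
#' to each condition (expression 0 in the other), and an asymmetric set of
#' differentially expressed genes among the common ones.
#'
#' @param n_common number of genes expressed in both conditions.
#' @param n_unique_1,n_unique_2 genes expressed only in condition 1 / 2.
#' @param prop_de fraction of common genes differentially expressed.
#' @param fold_change DE magnitude (linear, applied multiplicatively in the
#'   favoured condition).
#' @param prop_de_up_1 fraction of DE genes higher in condition 1.
#' @param library_sizes reads per simulated library: a scalar (recycled) or
#'   a vector of length `2 * n_reps` ordered condition 1 replicates first.
#' @param n_reps libraries per condition.
#' @param seed integer random seed; all randomness in
#'   [simulate_experiment()] flows from it.
#' @param source expression sampler from [build_source()] (default: the
#'   parametric fallback).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_common, n_unique_1 = 0, n_unique_2 = 0,
                       prop_de = 0, fold_change = 2, prop_de_up_1 = 0.5,
                       library_sizes = 1e6, n_reps = 1, seed = 1,
                       source = build_source()) {
  stopifnot(n_common >= 1, n_unique_1 >= 0, n_unique_2 >= 0,
            prop_de >= 0, prop_de <= 1, fold_change > 0,
            prop_de_up_1 >= 0, prop_de_up_1 <= 1,
            all(library_sizes > 0), n_reps >= 1,
            is.function(source))
  n_lib <- 2L * as.integer(n_reps)
  if (!length(library_sizes) %in% c(1L, n_lib))
    stop("'library_sizes' must have length 1 or 2 * n_reps")
  structure(list(n_common = as.integer(n_common),
                 n_unique_1 = as.integer(n_unique_1),
                 n_unique_2 = as.integer(n_unique_2),
                 prop_de = prop_de, fold_change = fold_change,
                 prop_de_up_1 = prop_de_up_1,
                 library_sizes = rep_len(library_sizes, n_lib),
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed), source = source),
            class = "sim_config")
}

#' Simulate a two-condition RNA-seq experiment with full ground truth
#'
#' Draws a base expression value per gene from the configured source,
#' assigns condition-unique genes (expression zero in the other condition)
#' and differentially expressed genes (expression multiplied by the fold
#' change in the favoured condition; `floor(prop_de * n_common)` genes, of
#' which `floor(prop_de_up_1 * n_de)` favour condition 1 — truth tables
#' record the realized fractions). The total RNA output of condition z is
#' S_z, the sum of its expression values; each library k of condition z then
#' receives independent Poisson counts with mean
#' \deqn{\mu_{gz} / S_z \cdot N_k}
#' so that a condition producing more RNA spreads the same sequencing depth
#' over more transcript — the composition bias the normalization must undo.
#'
#' All randomness comes from `config$seed`; draws occur in a fixed order
#' (base expression, DE direction assignment, then counts library by
#' library), so a configuration is fully reproducible. The caller's random
#' number generator state is left untouched.
#'
#' @param config a [sim_config()].
#' @return An object of class `"sim_experiment"`: list with `counts` (a
#'   [count_matrix()], libraries named `cond<z>_rep<i>`), `truth` (data
#'   frame: `gene`, `mu_1`, `mu_2`, `is_de`, `de_direction`, `unique_to`),
#'   `S` (true total RNA outputs, length 2), `true_production_ratio`
#'   (= S_1/S_2), `true_factor` (= S_2/S_1, the factor orientation of
#'   [tmm_pair()] for a condition-1 library against a condition-2
#'   reference), `design` (library -> condition), realized DE fractions,
#'   and the `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_total <- config$n_common + config$n_unique_1 + config$n_unique_2
  genes <- sprintf("g%0*d", nchar(n_total), seq_len(n_total))
  base <- as.numeric(config$source(n_total))
  if (any(base <= 0)) stop("expression source returned non-positive values")

  unique_to <- rep.int("none", n_total)
  if (config$n_unique_1 > 0)
    unique_to[config$n_common + seq_len(config$n_unique_1)] <- "1"
  if (config$n_unique_2 > 0)
    unique_to[config$n_common + config$n_unique_1 +
              seq_len(config$n_unique_2)] <- "2"

  n_de <- floor(config$prop_de * config$n_common)
  n_up1 <- floor(config$prop_de_up_1 * n_de)
  is_de <- rep.int(FALSE, n_total)
  de_dir <- rep.int("none", n_total)
  if (n_de > 0) {
    de_idx <- sample(config$n_common, n_de)
    up1 <- de_idx[seq_len(n_up1)]
    dn1 <- setdiff(de_idx, up1)
    is_de[de_idx] <- TRUE
    de_dir[up1] <- "1"
    de_dir[dn1] <- "2"
  }

  mu1 <- base; mu2 <- base
  mu1[unique_to == "2"] <- 0
  mu2[unique_to == "1"] <- 0
  mu1[de_dir == "1"] <- mu1[de_dir == "1"] * config$fold_change
  mu2[de_dir == "2"] <- mu2[de_dir == "2"] * config$fold_change
  S <- c(sum(mu1), sum(mu2))
  if (any(S == 0)) stop("a condition has no expressed genes (S = 0)")

  cond <- rep(c("1", "2"), each = config$n_reps)
  lib_ids <- paste0("cond", cond, "_rep", rep(seq_len(config$n_reps), 2L))
  counts <- matrix(0, n_total, length(lib_ids),
                   dimnames = list(genes, lib_ids))
  mu <- cbind(mu1, mu2)
  for (j in seq_along(lib_ids)) {
    z <- as.integer(cond[j])
    counts[, j] <- stats::rpois(n_total,
                                mu[, z] / S[z] * config$library_sizes[j])
  }

  truth <- data.frame(gene = genes, mu_1 = mu1, mu_2 = mu2, is_de = is_de,
                      de_direction = de_dir, unique_to = unique_to,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(counts = count_matrix(counts),
                 truth = truth,
                 S = stats::setNames(S, c("1", "2")),
                 true_production_ratio = S[1L] / S[2L],
                 true_factor = S[2L] / S[1L],
                 design = stats::setNames(cond, lib_ids),
                 realized_prop_de = n_de / config$n_common,
                 realized_prop_de_up_1 = if (n_de > 0) n_up1 / n_de else NA_real_,
                 config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cfg <- x$config
  cat("Simulated RNA-seq experiment: ", cfg$n_common, " common genes + ",
      cfg$n_unique_1, "/", cfg$n_unique_2, " unique, ",
      cfg$n_reps, " rep(s) per condition\n", sep = "")
  cat(sprintf("  true production ratio S_1/S_2 = %.4f (factor %.4f)\n",
              x$true_production_ratio, x$true_factor))
  cat(sprintf("  DE: %.1f%% of common genes (%.0f%% favouring condition 1) at %g-fold\n",
              100 * x$realized_prop_de,
              100 * (if (is.na(x$realized_prop_de_up_1)) 0 else x$realized_prop_de_up_1),
              cfg$fold_change))
  invisible(x)
}

#' True relative RNA production between two simulated conditions
#'
#' @param experiment a [simulate_experiment()] result.
#' @param k,r condition labels (`"1"` or `"2"`).
#' @return The exact truth ratio S_k / S_r.
#' @export
true_factor <- function(experiment, k = "1", r = "2") {
  stopifnot(inherits(experiment, "sim_experiment"))
  k <- as.character(k); r <- as.character(r)
  if (!k %in% names(experiment$S) || !r %in% names(experiment$S))
    stop("conditions must be \"1\" or \"2\"")
  if (experiment$S[[r]] == 0) stop("reference condition has zero RNA output")
  experiment$S[[k]] / experiment$S[[r]]
}
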