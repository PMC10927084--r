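# Phase-diagram grids and Monte Carlo mechanism surveys.

.ead_labels <- c("none", "repol_failure", "typeI", "typeII", "typeIII",
                 "typeIV", "diverged")

#' Phase diagram over the alpha(P_Ca)-alpha(G_Ks) plane
#'
#' Classifies the EAD mechanism on a grid of scaling factors for the L-type
#' Ca permeability and the slow delayed-rectifier conductance, at fixed
#' background scaling factors for the remaining adjustable parameters.
#' Divergent cells are recorded as the label `"diverged"`, not an error.
#'
#' @param alpha_PCa,alpha_GKs strictly increasing axis vectors of scaling
#'   factors.
#' @param background named vector of scaling factors for `k_max`,
#'   `J_Caslmyo`, `I_NCX_bar` (defaults 1).
#' @param protocol stimulation protocol.
#' @param fss inactivation-curve variant.
#' @param ... passed to [classify_ead_mechanism()].
#' @return A `phase_diagram` data.frame with columns `alpha_PCa`,
#'   `alpha_GKs`, `label`; axes and background in attributes.
#' @export
phase_diagram <- function(alpha_PCa, alpha_GKs,
                          background = c(k_max = 1, J_Caslmyo = 1,
                                         I_NCX_bar = 1),
                          protocol = stim_single(),
                          fss = c("original", "flattened"), ...) {
  fss <- match.arg(fss)
  if (is.unsorted(alpha_PCa, strictly = TRUE) ||
      is.unsorted(alpha_GKs, strictly = TRUE))
    stop("axes must be strictly increasing")
  grid <- expand.grid(alpha_PCa = alpha_PCa, alpha_GKs = alpha_GKs,
                      KEEP.OUT.ATTRS = FALSE)
  lab <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- c(background, P_Ca = grid$alpha_PCa[i], G_Ks = grid$alpha_GKs[i])
    cl <- classify_ead_mechanism(wg_params(alpha = a, fss = fss),
                                 protocol = protocol, ...)
    lab[i] <- cl$label
  }
  grid$label <- lab
  attr(grid, "background") <- background
  attr(grid, "fss") <- fss
  class(grid) <- c("phase_diagram", "data.frame")
  grid
}

#' Monte Carlo survey of EAD mechanisms
#'
#' Draws `n` independent vectors of scaling factors for the five adjustable
#' parameters (`k_max`, `J_Caslmyo`, `P_Ca`, `G_Ks`, `I_NCX_bar`), uniform
#' on the log scale over `range` by default, classifies each sample with a
#' single-stimulus protocol, and summarizes the fraction of each mechanism
#' among the EAD-positive samples.  Identical seeds give identical results.
#'
#' @param n number of parameter sets.
#' @param range multiplicative range `c(lo, hi)`, `lo > 0`.
#' @param seed integer seed for the sampler.
#' @param fss inactivation-curve variant (`"flattened"` reproduces the
#'   flattened-curve survey).
#' @param sampling `"log_uniform"` (default) or `"uniform"`.
#' @param t_end per-sample horizon (ms).
#' @param with_confirmatory run confirmatory clamps per sample (off by
#'   default in the survey for speed; the decision labels do not use them).
#' @param ... passed to [classify_ead_mechanism()].
#' @return A `monte_carlo_result`: per-sample alphas and labels, counts,
#'   and `fractions` over the four EAD types among EAD-positive samples
#'   (percent).
#' @export
monte_carlo_classification <- function(n, range = c(0.1, 10), seed = 1,
                                       fss = c("original", "flattened"),
                                       sampling = c("log_uniform", "uniform"),
                                       t_end = 10000,
                                       with_confirmatory = FALSE, ...) {
  fss <- match.arg(fss)
  sampling <- match.arg(sampling)
  if (n < 1) stop("n must be at least 1")
  if (range[1] <= 0 || range[2] < range[1]) stop("invalid range")
  set.seed(as.integer(seed))
  u <- matrix(runif(n * 5L), nrow = n, ncol = 5L,
              dimnames = list(NULL, .wg_alpha_names))
  alphas <- if (sampling == "log_uniform") {
    exp(log(range[1]) + u * (log(range[2]) - log(range[1])))
  } else {
    range[1] + u * (range[2] - range[1])
  }
  labels <- character(n)
  for (i in seq_len(n)) {
    cl <- classify_ead_mechanism(
      wg_params(alpha = alphas[i, ], fss = fss),
      protocol = stim_single(), t_end = t_end,
      with_confirmatory = with_confirmatory, ...)
    labels[i] <- cl$label
  }
  samples <- data.frame(alphas, label = labels)
  types <- c("typeI", "typeII", "typeIII", "typeIV")
  n_pos <- sum(labels %in% types)
  fractions <- if (n_pos > 0) {
    100 * vapply(types, function(tp) sum(labels == tp), 0) / n_pos
  } else stats::setNames(rep(NA_real_, 4), types)
  structure(list(seed = seed, n_samples = n, range = range, fss = fss,
                 sampling = sampling, samples = samples,
                 counts = table(factor(labels, levels = .ead_labels)),
                 n_ead_positive = n_pos, fractions = fractions),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf("<monte_carlo_result> n = %d (%s f_ss), EAD-positive = %d\n",
              x$n_samples, x$fss, x$n_ead_positive))
  print(x$counts)
  if (x$n_ead_positive > 0) {
    cat("fractions among EAD-positive (%):\n")
    print(round(x$fractions, 2))
  }
  invisible(x)
}
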