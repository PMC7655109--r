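# Interaction probabilities and Bayesian uncertainty.
#
# Occupancy probabilities are plain means over frames and subunits. Errors
# come from a two-state Markov model: transition counts are pooled across
# subunit series, each transition-probability row gets an independent
# Beta (i.e. two-state Dirichlet) posterior with symmetric prior mass, and
# the stationary probability p01/(p01+p10) is summarized over posterior
# draws.

#' Mean occupancy of one fingerprint bit
#'
#' Averages a bit over all sampled frames and all subunits, matching
#' residues across subunits by label.
#'
#' @param fp a `fingerprint_matrix`.
#' @param residue residue label (e.g. `"TRP156"`) or row index.
#' @param bit bit name from [fingerprint_bits] or index 1-9.
#' @return fraction in `[0, 1]`.
#' @export
occupancy_probability <- function(fp, residue, bit) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  r <- if (is.numeric(residue)) residue else match(residue, fp$residues$label)
  if (is.na(r) || r < 1 || r > nrow(fp$residues)) {
    stop("unknown residue: ", residue)
  }
  b <- if (is.numeric(bit)) bit else match(bit, fingerprint_bits)
  if (is.na(b) || b < 1 || b > 9) stop("unknown bit: ", bit)
  mean(fp$bits[r, b, , ])
}

#' Per-subunit binary series of one bit
#'
#' @inheritParams occupancy_probability
#' @return list of 0/1 integer vectors, one per subunit.
#' @export
bit_series <- function(fp, residue, bit) {
  r <- if (is.numeric(residue)) residue else match(residue, fp$residues$label)
  b <- if (is.numeric(bit)) bit else match(bit, fingerprint_bits)
  lapply(seq_along(fp$subunits), function(s) {
    as.integer(fp$bits[r, b, , s])
  })
}

#' Two-state Markov posterior for a binary occupancy series
#'
#' Transition counts are pooled across the supplied series (replicates);
#' no transition is counted across a series boundary. With symmetric prior
#' mass `prior_count` per transition cell, the posterior of each row is
#' `p01 ~ Beta(n01 + prior, n00 + prior)` and
#' `p10 ~ Beta(n10 + prior, n11 + prior)`. The stationary probability of
#' each draw is `p01 / (p01 + p10)`; its mean and equal-tailed credible
#' interval are reported.
#'
#' @param series a 0/1 vector or list of 0/1 vectors (one per subunit).
#' @param prior_count symmetric Dirichlet prior mass per cell (default 1,
#'   the conventional uniform prior).
#' @param n_samples posterior draws (default 10000, minimum 1000).
#' @param ci_level credible level (default 0.95).
#' @param seed integer seed; the estimate is seed-deterministic.
#' @return object of class `markov_estimate` with transition counts,
#'   `stationary_mean`, `ci_low`, `ci_high`, and the posterior draws.
#' @export
markov_error <- function(series, prior_count = 1, n_samples = 10000,
                         ci_level = 0.95, seed = 1) {
  if (!is.list(series)) series <- list(series)
  if (prior_count <= 0) stop("prior_count must be positive")
  if (n_samples < 1000) stop("n_samples must be at least 1000")
  counts <- c(n00 = 0L, n01 = 0L, n10 = 0L, n11 = 0L)
  for (s in series) {
    s <- as.integer(s)
    if (length(s) < 2L) stop("each series needs length >= 2")
    if (any(!s %in% c(0L, 1L))) stop("series values must be 0/1")
    from <- s[-length(s)]
    to <- s[-1L]
    counts["n00"] <- counts["n00"] + sum(from == 0L & to == 0L)
    counts["n01"] <- counts["n01"] + sum(from == 0L & to == 1L)
    counts["n10"] <- counts["n10"] + sum(from == 1L & to == 0L)
    counts["n11"] <- counts["n11"] + sum(from == 1L & to == 1L)
  }
  draws <- with_seed(seed, {
    p01 <- stats::rbeta(
      n_samples, counts["n01"] + prior_count, counts["n00"] + prior_count
    )
    p10 <- stats::rbeta(
      n_samples, counts["n10"] + prior_count, counts["n11"] + prior_count
    )
    # p01 + p10 == 0 has probability zero under a positive prior; guard by
    # rejection anyway since the stationary probability is undefined there.
    bad <- which(p01 + p10 <= 0)
    while (length(bad)) {
      p01[bad] <- stats::rbeta(
        length(bad), counts["n01"] + prior_count, counts["n00"] + prior_count
      )
      p10[bad] <- stats::rbeta(
        length(bad), counts["n10"] + prior_count, counts["n11"] + prior_count
      )
      bad <- which(p01 + p10 <= 0)
    }
    cbind(p01 = p01, p10 = p10)
  })
  stat <- draws[, "p01"] / (draws[, "p01"] + draws[, "p10"])
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE))
  structure(
    list(
      n00 = unname(counts["n00"]), n01 = unname(counts["n01"]),
      n10 = unname(counts["n10"]), n11 = unname(counts["n11"]),
      prior_count = prior_count, posterior_samples = draws,
      stationary_mean = mean(stat), ci_low = ci[1L], ci_high = ci[2L],
      ci_level = ci_level, seed = seed
    ),
    class = "markov_estimate"
  )
}

#' @export
print.markov_estimate <- function(x, ...) {
  cat(sprintf(
    "<markov_estimate> stationary %.4f [%.4f, %.4f] (%d%% CI), counts n00=%d n01=%d n10=%d n11=%d\n",
    x$stationary_mean, x$ci_low, x$ci_high, round(100 * x$ci_level),
    x$n00, x$n01, x$n10, x$n11
  ))
  invisible(x)
}

#' Stability class of an interaction probability
#'
#' Half-open, lower-exclusive bins: `very_stable` above 0.75, `stable`
#' above 0.50, `occasional` above 0.25, `rare` at or below 0.25.
#'
#' @param probability fraction in `[0, 1]`.
#' @return character label.
#' @export
stability_class <- function(probability) {
  if (any(probability < 0 | probability > 1)) {
    stop("probability must lie in [0, 1]")
  }
  cut(
    probability,
    breaks = c(-Inf, 0.25, 0.50, 0.75, Inf),
    labels = c("rare", "occasional", "stable", "very_stable"),
    right = TRUE
  ) |> as.character()
}

#' Summarize a fingerprint matrix
#'
#' For every (residue, bit): mean occupancy, Markov credible half-width,
#' and stability class.
#'
#' @param fp a `fingerprint_matrix`.
#' @param prior_count,n_samples,ci_level,seed passed to [markov_error()].
#' @param path optional CSV output path.
#' @return data.frame, one row per residue x bit.
#' @export
fingerprint_summary <- function(fp, prior_count = 1, n_samples = 10000,
                                ci_level = 0.95, seed = 1, path = NULL) {
  rows <- expand.grid(
    residue = seq_len(nrow(fp$residues)), bit = seq_len(9L),
    KEEP.OUT.ATTRS = FALSE
  )
  res <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows$residue[i]
    b <- rows$bit[i]
    p <- occupancy_probability(fp, r, b)
    est <- markov_error(
      bit_series(fp, r, b),
      prior_count = prior_count, n_samples = n_samples,
      ci_level = ci_level, seed = seed + i
    )
    data.frame(
      residue = fp$residues$label[r], chain = fp$residues$chain[r],
      bit = fingerprint_bits[b], probability = p,
      error = (est$ci_high - est$ci_low) / 2,
      ci_low = est$ci_low, ci_high = est$ci_high,
      stability = stability_class(p),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Simulate a two-state Markov chain
#'
#' Generative counterpart of [markov_error()]: a 0/1 chain with transition
#' probabilities `p01` (0 to 1) and `p10` (1 to 0).
#'
#' @param n chain length.
#' @param p01,p10 transition probabilities.
#' @param init initial state, or `"stationary"` to draw it from the
#'   stationary distribution.
#' @param seed integer seed.
#' @return integer 0/1 vector of length `n`.
#' @export
simulate_markov_chain <- function(n, p01, p10, init = "stationary", seed = 1) {
  stopifnot(p01 >= 0, p01 <= 1, p10 >= 0, p10 <= 1, n >= 1)
  with_seed(seed, {
    s <- integer(n)
    if (identical(init, "stationary")) {
      pi1 <- if (p01 + p10 > 0) p01 / (p01 + p10) else 0.5
      s[1L] <- stats::rbinom(1L, 1L, pi1)
    } else {
      s[1L] <- as.integer(init)
    }
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      for (i in 2L:n) {
        s[i] <- if (s[i - 1L] == 0L) {
          as.integer(u[i - 1L] < p01)
        } else {
          as.integer(u[i - 1L] >= p10)
        }
      }
    }
    s
  })
}
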