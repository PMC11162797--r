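# Minimal copolymerization competition model: per-step incorporation
# propensities per sugar, terminal-sugar-dependent extendability (an
# arabino terminus blocks further extension), exact Markov enumeration and
# Monte-Carlo sampling of product compositions.

#' Per-sugar incorporation propensity model
#'
#' `weights` are dimensionless relative incorporation propensities per
#' sugar; `extendability` maps each terminal sugar to the probability in
#' `[0, 1]` that a chain ending in it can be extended further. Defaults
#' encode the observed chemistry: an arabino terminus is a chain terminator
#' (extendability 0), a ribo terminus extends freely, and a threo terminus
#' is penalized (default 0.17, the ~6-fold rate reduction of activated
#' threo- versus ribo-guanosine mapped to a relative extendability).
#'
#' @param weights Named non-negative numeric vector, at least one positive.
#' @param extendability Named numeric vector in `[0, 1]` covering the same
#'   sugars.
#' @return A `propensity_model`.
#' @export
propensity_model <- function(weights,
                             extendability = c(ribo = 1, arabino = 0,
                                               threo = 0.17)) {
  stopifnot(!is.null(names(weights)), all(weights >= 0), sum(weights) > 0,
            all(extendability >= 0), all(extendability <= 1))
  miss <- setdiff(names(weights), names(extendability))
  if (length(miss)) {
    stop("extendability missing for: ", paste(miss, collapse = ", "))
  }
  structure(list(weights = weights,
                 extendability = extendability[names(weights)]),
            class = "propensity_model")
}

#' Monomer-pool composition
#'
#' @param x Named non-negative vector of input amounts or mole fractions;
#'   normalized to sum to 1.
#' @return A named fraction vector of class `pool_composition`.
#' @export
pool_composition <- function(x) {
  stopifnot(!is.null(names(x)), all(x >= 0), sum(x) > 0)
  structure(x / sum(x), class = "pool_composition")
}

#' Pool from an input ratio such as 10:1:1
#'
#' @param ratio Numeric ratio vector, e.g. `c(10, 1, 1)`.
#' @param sugars Sugar names, defaults to ribo/arabino/threo.
#' @return A [pool_composition()].
#' @export
pool_from_ratio <- function(ratio, sugars = c("ribo", "arabino", "threo")) {
  pool_composition(stats::setNames(ratio, sugars))
}

#' Predicted single-step incorporation fractions
#'
#' `f_i = w_i x_i / sum_j w_j x_j`: with equal weights the product
#' composition mirrors the input ratios; weights express the per-sugar
#' selection bias on top of availability.
#'
#' @param pm A [propensity_model()].
#' @param pool A [pool_composition()] over the same sugars.
#' @return Named fraction vector summing to 1.
#' @export
predict_step_fractions <- function(pm, pool) {
  stopifnot(inherits(pm, "propensity_model"),
            inherits(pool, "pool_composition"))
  w <- pm$weights[names(pool)]
  if (anyNA(w)) stop("pool sugars not covered by the propensity model")
  z <- w * unclass(pool)
  if (sum(z) == 0) stop("all weighted propensities are zero")
  z / sum(z)
}

#' Fit propensity weights from an observed composition
#'
#' Algebraic inverse of [predict_step_fractions()]: `w_i` proportional to
#' `f_i / x_i`, normalized to sum to 1. Round-trips exactly:
#' `predict_step_fractions(fit_weights(f, x), x) == f`.
#'
#' @param observed Named observed incorporation fractions (simplex).
#' @param pool The [pool_composition()] the observation was made under;
#'   must be positive wherever `observed` is.
#' @param extendability Passed to [propensity_model()].
#' @return A `propensity_model` with the fitted weights.
#' @export
fit_weights <- function(observed, pool,
                        extendability = c(ribo = 1, arabino = 0,
                                          threo = 0.17)) {
  stopifnot(inherits(pool, "pool_composition"),
            !is.null(names(observed)), all(observed >= 0))
  observed <- observed[names(pool)]
  if (anyNA(observed)) stop("observed fractions must cover the pool sugars")
  observed <- observed / sum(observed)
  if (any(observed > 0 & unclass(pool) == 0)) {
    stop("observed incorporation of a sugar absent from the pool")
  }
  w <- ifelse(unclass(pool) > 0, observed / unclass(pool), 0)
  propensity_model(w / sum(w), extendability)
}

#' Exact enumeration of chain-growth product distributions
#'
#' Memoryless Markov model: from any live chain, the next step either
#' terminates (probability `1 - e(terminal sugar)`) or appends sugar `i`
#' with probability `e(terminal) * f_i`, where `f` are the step fractions.
#' Chains start from the primer terminus (`primer_terminal`, default a
#' ribonucleotide, so extension is unimpeded). Both early-terminated chains
#' and chains reaching `depth` are reported; the probability mass sums
#' to 1.
#'
#' @param pm A [propensity_model()].
#' @param pool A [pool_composition()].
#' @param depth Maximum number of addition steps (>= 1).
#' @param primer_terminal Sugar of the primer's 3'-terminal residue.
#' @return Data frame: `sequence` (">"-separated added sugars, `""` for the
#'   unextended primer), `length`, `terminated` (logical: stopped before
#'   `depth`), `probability`.
#' @export
enumerate_products <- function(pm, pool, depth = 2,
                               primer_terminal = "ribo") {
  stopifnot(depth >= 1)
  f <- predict_step_fractions(pm, pool)
  e <- pm$extendability
  term_e <- function(s) if (s %in% names(e)) e[[s]] else 1
  done <- list()
  live <- list(list(seq = character(0), p = 1, term = primer_terminal))
  for (d in seq_len(depth)) {
    nxt <- list()
    for (ch in live) {
      pe <- term_e(ch$term)
      if (pe < 1) {
        done[[length(done) + 1]] <- list(seq = ch$seq,
                                         p = ch$p * (1 - pe),
                                         terminated = TRUE)
      }
      if (pe > 0) {
        for (s in names(f)) {
          nxt[[length(nxt) + 1]] <- list(seq = c(ch$seq, s),
                                         p = ch$p * pe * f[[s]], term = s)
        }
      }
    }
    live <- nxt
  }
  for (ch in live) {
    done[[length(done) + 1]] <- list(seq = ch$seq, p = ch$p,
                                     terminated = FALSE)
  }
  out <- data.frame(
    sequence = vapply(done, function(x) paste(x$seq, collapse = ">"), ""),
    length = vapply(done, function(x) length(x$seq), integer(1)),
    terminated = vapply(done, `[[`, logical(1), "terminated"),
    probability = vapply(done, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out[order(-out$probability), ]
}

#' Composition among chains of a given length
#'
#' Conditions [enumerate_products()] on chains of exactly `length` added
#' residues — either all of them or only full-depth survivors — and
#' renormalizes, giving e.g. the expected +2 product profile.
#'
#' @param products An [enumerate_products()] table.
#' @param length Chain length to condition on.
#' @return Data frame `sequence`, `probability` (renormalized).
#' @export
conditional_composition <- function(products, length) {
  sel <- products[products$length == length, , drop = FALSE]
  if (!nrow(sel) || sum(sel$probability) == 0) {
    stop("no probability mass at length ", length)
  }
  sel$probability <- sel$probability / sum(sel$probability)
  sel[, c("sequence", "probability")]
}

#' Monte-Carlo twin of [enumerate_products()]
#'
#' @param pm,pool,depth,primer_terminal As in [enumerate_products()].
#' @param n Number of chains to sample.
#' @param seed Optional seed for reproducibility.
#' @return Data frame `sequence`, `length`, `terminated`, `probability`
#'   (empirical frequencies).
#' @export
sample_chains <- function(pm, pool, depth = 2, n = 1e4, seed = NULL,
                          primer_terminal = "ribo") {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- predict_step_fractions(pm, pool)
  e <- pm$extendability
  sugars <- names(f)
  seqs <- character(n); terminated <- logical(n)
  for (i in seq_len(n)) {
    term <- primer_terminal
    added <- character(0)
    stopped <- FALSE
    for (d in seq_len(depth)) {
      pe <- if (term %in% names(e)) e[[term]] else 1
      if (stats::runif(1) > pe) { stopped <- TRUE; break }
      s <- sample(sugars, 1, prob = f)
      added <- c(added, s)
      term <- s
    }
    seqs[i] <- paste(added, collapse = ">")
    terminated[i] <- stopped
  }
  agg <- as.data.frame(table(sequence = seqs), stringsAsFactors = FALSE)
  agg$probability <- agg$Freq / n
  agg$length <- lengths(strsplit(agg$sequence, ">", fixed = TRUE))
  agg$terminated <- vapply(agg$sequence, function(s) {
    any(terminated[seqs == s])
  }, logical(1))
  agg[order(-agg$probability), c("sequence", "length", "terminated",
                                 "probability")]
}

#' Total-variation distance between two product distributions
#'
#' @param a,b Data frames with `sequence` and `probability`.
#' @return TV distance in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  keys <- union(a$sequence, b$sequence)
  pa <- stats::setNames(rep(0, length(keys)), keys)
  pb <- pa
  pa[a$sequence] <- a$probability
  pb[b$sequence] <- b$probability
  sum(abs(pa - pb)) / 2
}
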