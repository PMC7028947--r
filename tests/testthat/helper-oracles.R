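# Independent oracles used across the suite.  These are deliberately
# brute-force and share no code with the implementation they check.

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins: sum of hypergeometric point probabilities <= that of the
# observed table (with a relative tolerance for ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by explicit pair counting (ties score 1/2).
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Non-negative least squares by active-set enumeration: for every subset of
# columns solve the unconstrained least-squares problem, keep feasible
# solutions, and return the best.  Exact for small catalogues.
oracle_nnls <- function(P, y) {
  k <- ncol(P)
  best <- rep(0, k); best_rss <- sum(y^2)
  for (bits in 1:(2^k - 1)) {
    idx <- which(bitwAnd(bits, 2^(0:(k - 1))) > 0)
    sol <- tryCatch(qr.solve(P[, idx, drop = FALSE], y), error = function(e) NULL)
    if (is.null(sol) || any(sol < -1e-10)) next
    w <- rep(0, k); w[idx] <- pmax(sol, 0)
    rss <- sum((y - P %*% w)^2)
    if (rss < best_rss - 1e-12) { best <- w; best_rss <- rss }
  }
  best
}

# Random 2x2 table with total at most n_max and at least one positive margin.
random_table <- function(n_max = 60) {
  repeat {
    cells <- as.integer(stats::rmultinom(1, sample.int(n_max, 1), prob = stats::runif(4, 0.05, 1)))
    if (sum(cells) > 0) return(cells)
  }
}

# Minimal variant-row factory for rule tests.
make_variant <- function(patient_id = "P1", gene = "TP53",
                         consequence = "missense", population_af = NA_real_,
                         sift_call = "unknown", polyphen_call = "unknown",
                         cosmic_count = 0L, in_oncokb = FALSE,
                         in_hotspot_catalog = FALSE,
                         trinucleotide_context = NA_character_,
                         ref = NA_character_, alt = NA_character_,
                         in_helicase_domain = FALSE) {
  data.frame(patient_id = patient_id, gene = gene, chrom = "chr1", pos = 100L,
             ref = ref, alt = alt, consequence = consequence,
             population_af = population_af, sift_call = sift_call,
             polyphen_call = polyphen_call, cosmic_count = cosmic_count,
             in_oncokb = in_oncokb, in_hotspot_catalog = in_hotspot_catalog,
             trinucleotide_context = trinucleotide_context,
             in_helicase_domain = in_helicase_domain, stringsAsFactors = FALSE)
}

make_variants <- function(...) do.call(rbind, list(...))

make_cnv <- function(patient_id = "P1", gene, call, copy_number = NA_real_) {
  data.frame(patient_id = patient_id, gene = gene, call = call,
             copy_number = copy_number, stringsAsFactors = FALSE)
}
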