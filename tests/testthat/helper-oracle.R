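# Independent oracles, deliberately naive: exact rational arithmetic and
# plain nested loops written straight from the defining formulas.  They share
# no code with the package implementation.

# --- exact rationals (numerator/denominator pairs; integers stay < 2^53) ---

rat <- function(n, d = 1) {
  n <- unname(n); d <- unname(d)
  stopifnot(d != 0)
  if (d < 0) { n <- -n; d <- -d }
  g <- rat_gcd(abs(n), d)
  c(n = n / max(g, 1), d = d / max(g, 1))
}

rat_gcd <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat_add <- function(x, y) rat(x["n"] * y["d"] + y["n"] * x["d"], x["d"] * y["d"])
rat_mul <- function(x, y) rat(x["n"] * y["n"], x["d"] * y["d"])
rat_div <- function(x, y) rat(x["n"] * y["d"], x["d"] * y["n"])
rat_sum <- function(xs) Reduce(rat_add, xs, rat(0))
rat_dbl <- function(x) unname(x["n"] / x["d"])

# --- nested-loop persistence oracle over a state matrix ------------------
# states: reads x introns, 0 uncovered / 1 retained / 2 spliced.
# Returns P_it per intron as a double (computed exactly, converted once).

oracle_persistence <- function(states, mean_denominator = "assigned",
                               sf_single = 1) {
  n_reads <- nrow(states); n_int <- ncol(states)
  sapply(seq_len(n_int), function(i) {
    covered <- sum(states[, i] != 0)
    d_i <- rat(covered, n_reads)
    total <- rat(0)
    for (r in seq_len(n_reads)) {
      if (states[r, i] != 1) next            # R_{r,i} = 0 contributes nothing
      # spliced fraction over introns spanned by r, target excluded
      I_r <- which(states[r, ] != 0)
      sf <- if (length(I_r) == 1L) rat(sf_single) else
        rat(sum(states[r, I_r] == 2) + 1 - 1, length(I_r) - 1)
      # Hamming similarity: reads spanning i with the same state at i
      comp <- which(states[, i] == states[r, i])
      terms <- lapply(comp, function(r2) {
        shared <- which(states[r, ] != 0 & states[r2, ] != 0)
        rat(sum(states[r, shared] == states[r2, shared]), length(shared))
      })
      h <- rat_div(rat_sum(terms), rat(length(comp)))
      total <- rat_add(total, rat_mul(sf, h))
    }
    D <- if (mean_denominator == "assigned") n_reads else max(covered, 1)
    rat_dbl(rat_mul(d_i, rat_div(total, rat(D))))
  })
}

# --- brute-force per-base exon overlap oracle -----------------------------

oracle_exon_overlap <- function(intron_start, intron_end, exons,
                                own_transcript) {
  ex <- exons[exons$transcript_id != own_transcript, , drop = FALSE]
  depth <- integer(intron_end - intron_start)
  n_over <- 0L
  for (k in seq_len(nrow(ex))) {
    hit_bases <- 0L
    for (b in seq.int(intron_start, intron_end - 1L)) {
      if (b >= ex$start[k] && b < ex$end[k]) {
        depth[b - intron_start + 1L] <- depth[b - intron_start + 1L] + 1L
        hit_bases <- hit_bases + 1L
      }
    }
    if (hit_bases > 0L) n_over <- n_over + 1L
  }
  list(n_overlapping_exons = n_over,
       pct_bases_overlapped = 100 * sum(depth > 0) / length(depth),
       max_overlap_depth = max(depth, 0L))
}

# --- textbook Fleiss' kappa from the category-count matrix ----------------

oracle_fleiss <- function(calls) {
  # counts per subject per category
  N <- nrow(calls); n <- ncol(calls)
  nij <- cbind(rowSums(calls == 1), rowSums(calls == 0))
  Pi <- (rowSums(nij^2) - n) / (n * (n - 1))
  pj <- colSums(nij) / (N * n)
  Pbar <- mean(Pi); Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}
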