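# Shared fixtures and independent oracles, all built in code at test time.

new_track <- fourcquant:::new_score_track
new_map <- fourcquant:::new_fragment_map

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Contiguous equal-length fragments carrying the given scores.
toy_track <- function(scores, chrom = "chrT", frag_len = 100,
                      stage = "raw", bait = NULL) {
  n <- length(scores)
  df <- tibble::tibble(chrom = chrom, start = (0:(n - 1)) * frag_len,
                       end = (1:n) * frag_len, index = 1:n,
                       blind_left = FALSE, blind_right = FALSE,
                       score = as.numeric(scores))
  new_track(df, stage = stage, bait = bait)
}

# Fragments of width `w` centered on the given midpoints.
track_at <- function(mids, scores, chrom = "chrT", w = 10,
                     stage = "normalized", bait = NULL) {
  o <- order(mids)
  mids <- mids[o]
  scores <- scores[o]
  df <- tibble::tibble(chrom = chrom, start = mids - w / 2,
                       end = mids + w / 2, index = seq_along(mids),
                       blind_left = FALSE, blind_right = FALSE,
                       score = as.numeric(scores))
  new_track(df, stage = stage, bait = bait)
}

toy_map <- function(bounds, chrom = "chrT", blind = FALSE) {
  n <- length(bounds) - 1
  new_map(tibble::tibble(chrom = chrom, start = bounds[-length(bounds)],
                         end = bounds[-1], index = 1:n,
                         blind_left = rep_len(blind, n),
                         blind_right = rep_len(blind, n)),
          contig_lengths = stats::setNames(max(bounds), chrom))
}

point_region <- function(center, chrom = "chrT", w = 100,
                         name = "bait") {
  region(chrom, center - w / 2, center + w / 2, name)
}

# Naive all-positions substring scan: the digestion oracle.
naive_motif_scan <- function(seq, motif, cut_offset) {
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  n <- length(chars)
  if (n < k) return(numeric(0))
  idx <- seq_len(n - k + 1)
  ok <- rep(TRUE, length(idx))
  for (j in seq_len(k)) ok <- ok & chars[idx + j - 1] == m[j]
  (idx[ok] - 1) + cut_offset
}

# Brute-force two-tailed Mann-Whitney p over all C(n1+n2, n1) labelings.
mw_enum_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  m <- n1 * length(y) / 2
  const <- n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - const
  combos <- utils::combn(length(pool), n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - const
  mean(abs(u_all - m) >= abs(u_obs - m) - 1e-9)
}

# The 2 Mb synthetic experiment is expensive to build; share one copy.
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$map)) {
    .shared$cfg <- simulation_config(seed = 1)
    .shared$genome <- make_toy_genome(.shared$cfg)
    .shared$map <- digest_genome(.shared$genome)
  }
  list(cfg = .shared$cfg, genome = .shared$genome, map = .shared$map)
}

# All processing stages for every replicate of every condition.
proc_conditions <- function(sims, excluded) {
  lapply(sims, function(reps) {
    lapply(reps, process_replicate, excluded = excluded)
  })
}

# Power-law decay fixtures: a bait at 100 kb and fragments at chosen
# distances d downstream, so distances equal the d values exactly.
decay_origin <- 100000
decay_bait <- function() point_region(decay_origin, w = 2)
decay_track <- function(d, s, stage = "normalized") {
  track_at(decay_origin + d, s, w = 2, stage = stage, bait = decay_bait())
}
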