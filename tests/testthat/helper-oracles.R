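# Independent reference implementations used to cross-check the package.
# These are deliberately written as plain loops / regex scans, not via the
# package's own code paths.

# Rank-mean quantile normalization for matrices without ties.
oracle_quantile_normalize <- function(mat) {
  target <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- target[rank(mat[, j])]
  out
}

# Straight-line reimplementation of the four screening rules on a small
# normalized long table. Returns the candidate sets at each stage.
oracle_screen <- function(norm, samples, floor = 6, fc_thr = 1.5) {
  mirnas <- unique(norm$mirna_id)
  lines <- unique(samples$cell_line)
  status <- samples$her2_status[match(lines, samples$cell_line)]
  val <- function(m, l, tr) {
    ids <- samples$sample_id[samples$cell_line == l & samples$treatment == tr]
    mean(norm$log2_intensity[norm$mirna_id == m & norm$sample_id %in% ids])
  }
  fc <- matrix(NA_real_, length(mirnas), length(lines),
               dimnames = list(mirnas, lines))
  expressed <- character()
  for (m in mirnas) {
    ok <- TRUE
    for (l in lines) {
      t <- val(m, l, "treated"); c <- val(m, l, "control")
      fc[m, l] <- t - c
      if (max(t, c) <= floor) ok <- FALSE
    }
    if (ok) expressed <- c(expressed, m)
  }
  neg <- lines[status == "negative"]
  pos <- lines[status == "positive"]
  survivors <- character()
  for (m in expressed) {
    changed <- FALSE
    for (l in neg) {
      if (2^fc[m, l] > fc_thr || 2^fc[m, l] < 1 / fc_thr) changed <- TRUE
    }
    if (!changed) survivors <- c(survivors, m)
  }
  up_per_line <- list(); down_per_line <- list()
  cross_up <- character(); cross_down <- character()
  for (l in pos) { up_per_line[[l]] <- character(); down_per_line[[l]] <- character() }
  for (m in survivors) {
    neg_mean <- mean(fc[m, neg])
    rfcs <- numeric()
    for (l in pos) {
      rfc <- 2^(fc[m, l] - neg_mean)
      rfcs <- c(rfcs, rfc)
      if (rfc > fc_thr) up_per_line[[l]] <- c(up_per_line[[l]], m)
      if (rfc < 1 / fc_thr) down_per_line[[l]] <- c(down_per_line[[l]], m)
    }
    mean_rfc <- exp(mean(log(rfcs)))
    if (mean_rfc > fc_thr) cross_up <- c(cross_up, m)
    if (mean_rfc < 1 / fc_thr) cross_down <- c(cross_down, m)
  }
  list(expressed = expressed, survivors = survivors,
       up_per_line = up_per_line, down_per_line = down_per_line,
       cross_up = cross_up, cross_down = cross_down)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Regex/substring scan for canonical sites, suppressing lower-grade calls
# contained in a higher-grade site's interval.
oracle_seed_sites <- function(utr, mirna) {
  utr <- chartr("U", "T", toupper(utr))
  seed7 <- chartr("U", "T", toupper(substr(mirna, 2, 8)))
  seed6 <- substr(seed7, 1, 6)
  motifs <- list(
    `8mer` = paste0(oracle_revcomp(seed7), "A"),
    `7mer-m8` = oracle_revcomp(seed7),
    `7mer-A1` = paste0(oracle_revcomp(seed6), "A"),
    `6mer` = oracle_revcomp(seed6)
  )
  all_matches <- function(pat) {
    n <- nchar(pat)
    hits <- integer()
    for (i in seq_len(max(0, nchar(utr) - n + 1))) {
      if (substr(utr, i, i + n - 1) == pat) hits <- c(hits, i)
    }
    hits
  }
  out <- data.frame(start = integer(), end = integer(), site_type = character())
  for (type in names(motifs)) {
    n <- nchar(motifs[[type]])
    for (p in all_matches(motifs[[type]])) {
      s <- p - 1L; e <- p + n - 1L     # 0-based half-open
      contained <- any(out$start <= s & out$end >= e)
      if (!contained) out <- rbind(out, data.frame(start = s, end = e, site_type = type))
    }
  }
  out[order(out$start), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
random_mirna <- function(len = 22) paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")

# small fully specified simulated experiment used by several tests
tiny_sim <- function(...) {
  simulate_array(array_sim_config(
    n_mirnas = 30, noise_log2_sd = 0, low_expression_fraction = 0,
    line_effect_log2_sd = 0, rng_seed = 42, ...
  ))
}
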