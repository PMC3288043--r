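#' Seed region of a mature microRNA
#'
#' Nucleotides 2-8 of the mature sequence (7 nt), the primary determinant
#' of canonical target-site recognition. For the miR-30 family this is
#' `GUAAACA`.
#'
#' @param mirna_seq Mature microRNA sequence, 5' to 3', RNA or DNA alphabet.
#' @return The 7-nt seed as an uppercase RNA string.
#' @export
mirna_seed <- function(mirna_seq) {
  s <- check_nucleotides(mirna_seq, to = "RNA")
  if (nchar(s) < 8) {
    abort("Mature microRNA sequence must be at least 8 nt.",
          class = "mirscreen_format_error")
  }
  substr(s, 2, 8)
}

#' Scan a 3'UTR for canonical microRNA seed-match sites
#'
#' Finds Watson-Crick matches to the microRNA seed on the sense strand of
#' the UTR and reports the maximal site type at each locus:
#' * `8mer` — match to miRNA nt 2-8 plus an A opposite nt 1;
#' * `7mer-m8` — match to nt 2-8;
#' * `7mer-A1` — match to nt 2-7 plus the A;
#' * `6mer` — match to nt 2-7 only.
#'
#' Every canonical site contains the 6-nt core match (to nt 2-7); each core
#' occurrence is therefore classified once, into its highest-grade type, so
#' lower-grade calls inside a reported higher-grade site are suppressed.
#' Coordinates are 0-based half-open on the UTR; U and T are equivalent.
#'
#' @param utr_seq 3'UTR sequence (DNA or RNA).
#' @param mirna_seq Mature microRNA sequence, 5' to 3'.
#' @return Tibble `start`, `end`, `site_type`, `site_seq`, ordered by
#'   `start`. Zero rows when there is no site.
#' @examples
#' find_seed_sites("AAATGTTTACAAA", "UGUAAACAUCCUACACUCAGCU") # miR-30b, one 8mer
#' @export
find_seed_sites <- function(utr_seq, mirna_seq) {
  utr <- check_nucleotides(utr_seq, to = "DNA")
  seed <- mirna_seed(mirna_seq)                       # nt 2-8, RNA
  m8_motif <- revcomp_dna(chartr("U", "T", seed))     # 7 nt, ends with core
  core <- substr(m8_motif, 2, 7)                      # revcomp of nt 2-7

  starts <- str_locate_all_starts(utr, core)
  if (length(starts) == 0) {
    return(tibble(start = integer(), end = integer(),
                  site_type = character(), site_seq = character()))
  }
  sites <- purrr::map_dfr(starts, function(p) {       # p: 1-based core start
    has_m8 <- p > 1 && substr(utr, p - 1, p - 1) == substr(m8_motif, 1, 1)
    has_a1 <- p + 6 <= nchar(utr) && substr(utr, p + 6, p + 6) == "A"
    if (has_m8 && has_a1) {
      tibble(start = p - 2L, end = p + 6L, site_type = "8mer")
    } else if (has_m8) {
      tibble(start = p - 2L, end = p + 5L, site_type = "7mer-m8")
    } else if (has_a1) {
      tibble(start = p - 1L, end = p + 6L, site_type = "7mer-A1")
    } else {
      tibble(start = p - 1L, end = p + 5L, site_type = "6mer")
    }
  })
  sites$site_seq <- substr(rep(utr, nrow(sites)), sites$start + 1, sites$end)
  dplyr::arrange(sites, .data$start)
}

#' Disrupt selected seed sites by point mutation
#'
#' Introduces three transversions inside each selected site's core
#' seed-pairing region so that rescanning the mutated UTR finds no site of
#' any type at those loci; all other positions, and any unselected sites,
#' are left intact. The mutated positions are chosen deterministically from
#' `rng_seed`; if a mutation accidentally creates a new overlapping match,
#' another position set is drawn (up to 25 attempts).
#'
#' @param utr_seq The UTR the sites were found on.
#' @param mirna_seq The microRNA used for the scan.
#' @param sites Subset of the rows returned by [find_seed_sites()] for this
#'   UTR to disrupt (may be zero rows).
#' @param rng_seed Integer seed for the position draw.
#' @return A list of class `mutated_construct`: `sequence` (mutated UTR),
#'   `edits` (tibble `position` 0-based, `from`, `to`), `disrupted_sites`
#'   (the input sites).
#' @export
mutate_seed_sites <- function(utr_seq, mirna_seq, sites, rng_seed = 1L) {
  utr <- check_nucleotides(utr_seq, to = "DNA")
  found <- find_seed_sites(utr, mirna_seq)
  if (nrow(sites) > 0) {
    key <- paste(sites$start, sites$end, sites$site_type)
    if (!all(key %in% paste(found$start, found$end, found$site_type))) {
      abort("`sites` do not match sites found on this UTR (stale coordinates?).",
            class = "mirscreen_contract_error")
    }
  }
  transversion <- c(A = "C", C = "A", G = "T", T = "G")
  seq_chars <- strsplit(utr, "")[[1]]
  edits <- tibble(position = integer(), from = character(), to = character())

  withr::with_seed(rng_seed, {
    for (k in seq_len(nrow(sites))) {
      site <- sites[k, ]
      # core seed-pairing region: the 6-nt match to miRNA nt 2-7
      core_start <- site$end - ifelse(site$site_type %in% c("8mer", "7mer-A1"), 7L, 6L)
      core_pos <- (core_start + 1):(core_start + 6)    # 1-based
      for (attempt in 1:25) {
        pick <- sort(sample(core_pos, 3))
        trial <- seq_chars
        trial[pick] <- transversion[trial[pick]]
        trial_seq <- paste(trial, collapse = "")
        new_sites <- find_seed_sites(trial_seq, mirna_seq)
        hit_here <- any(new_sites$end > site$start & new_sites$start < site$end)
        if (!hit_here) {
          edits <- dplyr::bind_rows(edits, tibble(
            position = pick - 1L, from = seq_chars[pick],
            to = trial[pick]
          ))
          seq_chars <- trial
          break
        }
        if (attempt == 25) {
          abort("Could not disrupt a site without creating a new one.",
                class = "mirscreen_fit_error")
        }
      }
    }
  })
  structure(
    list(sequence = paste(seq_chars, collapse = ""), edits = edits,
         disrupted_sites = sites),
    class = "mutated_construct"
  )
}

#' @export
print.mutated_construct <- function(x, ...) {
  cat("<mutated_construct> ", nrow(x$disrupted_sites), " site(s) disrupted, ",
      nrow(x$edits), " edits\n", sep = "")
  invisible(x)
}

#' Group microRNAs into seed families
#'
#' MicroRNAs sharing an identical seed (nt 2-8) belong to one family and
#' recognize the same canonical sites; all five miR-30 family members, for
#' instance, share the seed `GUAAACA`.
#'
#' @param mirnas Tibble with columns `name` and `sequence`.
#' @return The input with added columns `seed` and `family` (integer id,
#'   ordered by first appearance).
#' @export
seed_family <- function(mirnas) {
  stopifnot(all(c("name", "sequence") %in% names(mirnas)))
  out <- dplyr::mutate(as_tibble(mirnas),
                       seed = purrr::map_chr(.data$sequence, mirna_seed))
  out$family <- match(out$seed, unique(out$seed))
  out
}

# --- sequence helpers -------------------------------------------------------

check_nucleotides <- function(seq, to = c("DNA", "RNA")) {
  to <- match.arg(to)
  if (length(seq) != 1 || !is.character(seq)) {
    abort("Sequence must be a single character string.",
          class = "mirscreen_format_error")
  }
  s <- toupper(seq)
  if (grepl("[^ACGTU]", s)) {
    abort("Sequence contains characters outside A/C/G/T/U.",
          class = "mirscreen_format_error")
  }
  if (to == "DNA") chartr("U", "T", s) else chartr("T", "U", s)
}

revcomp_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# all 1-based start positions of fixed pattern `pat` in `s`, overlaps allowed
str_locate_all_starts <- function(s, pat) {
  out <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  out
}
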