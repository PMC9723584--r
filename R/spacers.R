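# CRISPR array detection and spacer-to-protospacer matching. Matching is
# substitution-only (Hamming): the dual acceptance rule is expressed purely
# in match length and mismatch count, so gapped alignment is out of scope.

#' Detect CRISPR repeat-spacer arrays
#'
#' Desk-scale near-identical-repeat scanner: exact seed words of the minimum
#' repeat length are located, chained at spacings compatible with the
#' repeat/spacer length ranges, and extended outward while every copy stays
#' within `max_repeat_mismatch` Hamming distance of the first copy. Arrays
#' need at least `min_repeats` repeat copies (>= 2 spacers); reporting is
#' deterministic and leftmost-first, and arrays never overlap. Copies whose
#' seed word is disrupted by mismatches in every position are missed — with
#' exact repeats (the generator default) detection is exact.
#'
#' @param genome one-row genome table.
#' @param min_repeats minimum number of repeat copies.
#' @param repeat_len allowed repeat length range (bp).
#' @param spacer_len allowed spacer length range (bp).
#' @param max_repeat_mismatch Hamming tolerance of each copy to the first.
#' @return a tibble with one row per array: `genome_id`, `array_id`, `start`,
#'   `end` (0-based half-open), `n_repeats`, `repeat_consensus`, and a
#'   list-column `spacers` of tibbles (`spacer_id`, `sequence`, `start`,
#'   `end`). Zero rows when no array is found.
#' @export
detect_arrays <- function(genome, min_repeats = 3L, repeat_len = c(21L, 48L),
                          spacer_len = c(18L, 72L), max_repeat_mismatch = 2L) {
  seq <- genome$sequence[1]
  gid <- genome$genome_id[1]
  L <- nchar(seq)
  k <- repeat_len[1]
  empty <- tibble(genome_id = character(), array_id = character(),
                  start = integer(), end = integer(), n_repeats = integer(),
                  repeat_consensus = character(), spacers = list())
  if (L < min_repeats * (k + spacer_len[1])) return(empty)
  chars <- strsplit(seq, "")[[1]]
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  occ <- occ[lengths(occ) >= min_repeats]
  if (length(occ) == 0) return(empty)
  occ <- occ[order(vapply(occ, min, integer(1)))]
  consumed <- rep(FALSE, L)
  gap_min <- k + spacer_len[1]
  gap_max <- repeat_len[2] + spacer_len[2]
  arrays <- list()
  for (pos in occ) {
    pos <- pos[!consumed[pos]]
    if (length(pos) < min_repeats) next
    chain <- pos[1]
    last <- pos[1]
    for (p in pos[-1]) {
      gap <- p - last
      if (gap >= gap_min && gap <= gap_max) {
        chain <- c(chain, p)
        last <- p
      }
    }
    if (length(chain) < min_repeats) next
    s <- chain          # 1-based repeat start per copy
    len <- k
    mism <- rep(0L, length(s))
    min_gap <- function(s, len) min(diff(s)) - len
    # a column belongs to the repeat when it is near-unanimous across copies
    # (>= 80%) and keeps every copy within the per-copy Hamming budget;
    # spacer columns are random and fail the unanimity test immediately
    col_ok <- function(col) {
      modal <- max(table(col))
      modal / length(col) >= 0.8
    }
    # extend right
    while (len < repeat_len[2] && s[length(s)] + len <= L &&
           (length(s) == 1 || min_gap(s, len + 1L) >= spacer_len[1])) {
      nxt <- chars[s + len]
      m2 <- mism + (nxt != nxt[1])
      if (!col_ok(nxt) || any(m2 > max_repeat_mismatch)) break
      mism <- m2
      len <- len + 1L
    }
    # extend left
    while (len < repeat_len[2] && s[1] > 1L &&
           min_gap(s, len + 1L) >= spacer_len[1]) {
      prv <- chars[s - 1L]
      m2 <- mism + (prv != prv[1])
      if (!col_ok(prv) || any(m2 > max_repeat_mismatch)) break
      mism <- m2
      s <- s - 1L
      len <- len + 1L
    }
    sp_len <- diff(s) - len
    if (any(sp_len < spacer_len[1] | sp_len > spacer_len[2])) next
    copies <- substring(seq, s, s + len - 1L)
    cons <- apply(do.call(rbind, strsplit(copies, "")), 2, function(col) {
      tt <- sort(table(col), decreasing = TRUE)
      names(tt)[1]
    })
    ai <- length(arrays) + 1L
    sp_start <- head(s, -1L) + len          # 1-based spacer starts
    sp_end <- tail(s, -1L) - 1L             # 1-based inclusive ends
    spacers <- tibble(
      spacer_id = sprintf("%s_arr%d_sp%02d", gid, ai, seq_along(sp_start)),
      sequence = substring(seq, sp_start, sp_end),
      start = sp_start - 1L,
      end = sp_end
    )
    arrays[[ai]] <- tibble(
      genome_id = gid, array_id = sprintf("%s_arr%d", gid, ai),
      start = s[1] - 1L, end = s[length(s)] + len - 1L,
      n_repeats = length(s),
      repeat_consensus = paste(cons, collapse = ""),
      spacers = list(spacers)
    )
    consumed[s[1]:(s[length(s)] + len - 1L)] <- TRUE
  }
  if (length(arrays) == 0) return(empty)
  bind_rows(arrays) %>% arrange(.data$start)
}

#' Flatten detected arrays into one spacer table
#'
#' @param arrays output of [detect_arrays()] (rows may span genomes).
#' @return tibble with `spacer_id`, `sequence`, `genome_id`, `array_id`,
#'   `start`, `end`.
#' @export
array_spacers <- function(arrays) {
  if (nrow(arrays) == 0) {
    return(tibble(spacer_id = character(), sequence = character(),
                  genome_id = character(), array_id = character(),
                  start = integer(), end = integer()))
  }
  arrays %>%
    select("genome_id", "array_id", "spacers") %>%
    tidyr::unnest("spacers") %>%
    select("spacer_id", "sequence", "genome_id", "array_id", "start", "end")
}

# Best qualifying window on one diagonal. `mism` is the 0/1 mismatch vector
# along the overlap. Returns c(offset, length, mismatches) or NULL.
best_window_on_diagonal <- function(mism, len_a = 24L, mm_a = 1L,
                                    len_b = 30L, mm_b = 3L) {
  n <- length(mism)
  if (n < len_a) return(NULL)
  cum <- c(0L, cumsum(mism))
  # quick reject: any qualifying window contains a len_a-window with <= mm_b
  roll_a <- cum[(len_a + 1L):(n + 1L)] - cum[seq_len(n - len_a + 1L)]
  if (min(roll_a) > mm_b) return(NULL)
  max_run <- function(kmax) {
    best <- 0L
    i <- 1L
    cnt <- 0L
    for (j in seq_len(n)) {
      cnt <- cnt + mism[j]
      while (cnt > kmax) {
        cnt <- cnt - mism[i]
        i <- i + 1L
      }
      if (j - i + 1L > best) best <- j - i + 1L
    }
    best
  }
  cand_len <- 0L
  la <- max_run(mm_a)
  if (la >= len_a) cand_len <- la
  lb <- max_run(mm_b)
  if (lb >= len_b) cand_len <- max(cand_len, lb)
  if (cand_len == 0L) return(NULL)
  limit <- if (cand_len >= len_b) mm_b else mm_a
  wins <- cum[(cand_len + 1L):(n + 1L)] - cum[seq_len(n - cand_len + 1L)]
  ok <- which(wins <= limit)
  best <- ok[which.min(wins[ok])]   # min mismatches, leftmost on ties
  c(offset = best - 1L, length = cand_len, mismatches = wins[best])
}

match_one <- function(spacer_chars, target_chars, len_a, mm_a, len_b, mm_b) {
  ls <- length(spacer_chars)
  lt <- length(target_chars)
  if (ls < len_a || lt < len_a) return(NULL)
  # mismatch matrix rows = spacer positions
  M <- vapply(seq_len(ls), function(a) spacer_chars[a] != target_chars,
              logical(lt))              # lt x ls
  out <- list()
  for (d in (-(ls - len_a)):(lt - len_a)) {
    lo <- max(1L, 1L - d)
    hi <- min(ls, lt - d)
    if (hi - lo + 1L < len_a) next
    a_idx <- lo:hi
    mism <- M[cbind(a_idx + d, a_idx)]
    bw <- best_window_on_diagonal(as.integer(mism), len_a, mm_a, len_b, mm_b)
    if (is.null(bw)) next
    a0 <- lo + bw[["offset"]] - 1L       # 0-based offset in spacer
    out[[length(out) + 1L]] <- c(a0 = a0, b0 = a0 + d,
                                 length = bw[["length"]],
                                 mismatches = bw[["mismatches"]])
  }
  out
}

#' Match spacers against target genomes under the dual rule
#'
#' Reports, for every spacer/target pair, the Hamming-matched windows that
#' satisfy either branch of the dual rule: match length >= `len_a` with at
#' most `mm_a` mismatches (default 24 nt, <= 1), or length >= `len_b` with at
#' most `mm_b` mismatches (default 30 nt, <= 3). Both target strands are
#' searched. Qualifying windows that overlap on one (spacer, target, strand,
#' diagonal) locus are reduced to a single hit: maximal length, then minimal
#' mismatches, then leftmost.
#'
#' @param spacers tibble with `spacer_id`, `sequence` (ACGT only); spacers
#'   shorter than `len_a` are skipped with a warning.
#' @param targets genome table of candidate protospacer carriers.
#' @param len_a,mm_a,len_b,mm_b the dual-rule thresholds.
#' @return a tibble of hits: `spacer_id`, `target_genome_id`, `target_start`
#'   (0-based, forward strand of the target), `strand`, `match_length`,
#'   `mismatches`, `rule` (`"24nt_le1mm"` or `"30nt_le3mm"`),
#'   `spacer_offset` (0-based within the spacer as matched).
#' @export
match_spacers <- function(spacers, targets, len_a = 24L, mm_a = 1L,
                          len_b = 30L, mm_b = 3L) {
  check_genomes(targets)
  short <- spacers$spacer_id[nchar(spacers$sequence) < len_a]
  if (length(short)) {
    warn(paste0(length(short), " spacer(s) shorter than ", len_a,
                " nt skipped: ", paste(head(short, 3), collapse = ", ")))
    spacers <- filter(spacers, !.data$spacer_id %in% short)
  }
  if (any(grepl("[^ACGT]", spacers$sequence))) {
    abort("spacer sequences must be ACGT-only")
  }
  hits <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers[i, ]
    for (j in seq_len(nrow(targets))) {
      tg <- targets[j, ]
      t_chars <- strsplit(tg$sequence, "")[[1]]
      for (strand in c("+", "-")) {
        q <- if (strand == "+") sp$sequence else rev_comp(sp$sequence)
        found <- match_one(strsplit(q, "")[[1]], t_chars,
                           len_a, mm_a, len_b, mm_b)
        for (f in found) {
          rule <- if (f[["mismatches"]] <= mm_a && f[["length"]] >= len_a) {
            sprintf("%dnt_le%dmm", len_a, mm_a)
          } else {
            sprintf("%dnt_le%dmm", len_b, mm_b)
          }
          hits[[length(hits) + 1L]] <- tibble(
            spacer_id = sp$spacer_id, target_genome_id = tg$genome_id,
            target_start = f[["b0"]], strand = strand,
            match_length = f[["length"]], mismatches = f[["mismatches"]],
            rule = rule, spacer_offset = f[["a0"]])
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(spacer_id = character(), target_genome_id = character(),
                  target_start = integer(), strand = character(),
                  match_length = integer(), mismatches = integer(),
                  rule = character(), spacer_offset = integer()))
  }
  bind_rows(hits) %>%
    arrange(.data$spacer_id, .data$target_genome_id, .data$strand,
            .data$target_start)
}

#' Aggregate spacer hits into host predictions
#'
#' Phages whose genomes are matched by a host's spacers are predicted to
#' infect that host. An empty hit table is a valid outcome and yields an
#' empty prediction table.
#'
#' @param hits hit table from [match_spacers()].
#' @param spacer_to_host tibble mapping `spacer_id` to `host_genome_id`.
#' @param host_taxonomy optional tibble (`host_genome_id`, `taxonomy`).
#' @return tibble with `phage_genome_id`, `host_genome_id`, `taxonomy`,
#'   `n_hits`, sorted by phage then descending hits.
#' @export
predict_hosts <- function(hits, spacer_to_host, host_taxonomy = NULL) {
  if (nrow(hits) == 0) {
    return(tibble(phage_genome_id = character(), host_genome_id = character(),
                  taxonomy = character(), n_hits = integer()))
  }
  unmapped <- setdiff(hits$spacer_id, spacer_to_host$spacer_id)
  if (length(unmapped)) {
    abort(paste0("spacer not mapped to a host genome: ", unmapped[1]))
  }
  out <- hits %>%
    left_join(select(spacer_to_host, "spacer_id", "host_genome_id"),
              by = "spacer_id") %>%
    count(.data$target_genome_id, .data$host_genome_id, name = "n_hits") %>%
    rename(phage_genome_id = "target_genome_id")
  if (!is.null(host_taxonomy)) {
    out <- left_join(out, select(host_taxonomy, "host_genome_id", "taxonomy"),
                     by = "host_genome_id")
  } else {
    out$taxonomy <- NA_character_
  }
  out %>%
    select("phage_genome_id", "host_genome_id", "taxonomy", "n_hits") %>%
    arrange(.data$phage_genome_id, desc(.data$n_hits), .data$host_genome_id)
}
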