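# Brute-force oracles and small builders shared across tests. Oracles are
# deliberately written as direct enumerations, independent of the package's
# vectorised implementations.

make_genome <- function(genome_id, sequence, circular = FALSE) {
  tibble::tibble(genome_id = genome_id, sequence = sequence,
                 circular = circular, description = "")
}

make_aln <- function(target_id, starts, lens, mismatches = 0L,
                     read_length = NULL, is_rna = FALSE) {
  n <- length(starts)
  if (is.null(read_length)) read_length <- lens
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    target_id = target_id,
    target_start = as.integer(starts),
    read_length = as.integer(rep_len(read_length, n)),
    mismatches = as.integer(rep_len(mismatches, n)),
    is_rna = is_rna,
    blocks = lapply(seq_len(n), function(i) {
      cbind(start = as.integer(starts[i]), end = as.integer(starts[i] + lens[i]))
    })
  )
}

# Per-position boolean-array breadth/covered-bases oracle.
oracle_position_flags <- function(alignments, L) {
  flags <- logical(L)
  for (m in alignments$blocks) {
    for (r in seq_len(nrow(m))) {
      if (m[r, "end"] > m[r, "start"]) {
        flags[(m[r, "start"] + 1):m[r, "end"]] <- TRUE
      }
    }
  }
  flags
}

# Enumeration oracle for the dual spacer rule: every (spacer offset, window
# length, target offset, strand) checked by direct character comparison,
# then reduced per (strand, diagonal) locus: max length, min mismatches,
# leftmost.
oracle_spacer_hits <- function(spacer, target, len_a = 24L, mm_a = 1L,
                               len_b = 30L, mm_b = 3L) {
  tch <- strsplit(target, "")[[1]]
  lt <- length(tch)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else phagecontext::rev_comp(spacer)
    qch <- strsplit(q, "")[[1]]
    ls <- length(qch)
    if (ls < len_a || lt < len_a) next
    for (a0 in 0:(ls - len_a)) {
      for (L in len_a:(ls - a0)) {
        if (lt < L) next
        pat <- qch[(a0 + 1):(a0 + L)]
        mm <- integer(lt - L + 1)
        for (p in seq_len(L)) {
          mm <- mm + (tch[p:(lt - L + p)] != pat[p])
        }
        qual <- (L >= len_a & mm <= mm_a) | (L >= len_b & mm <= mm_b)
        for (b0 in which(qual) - 1L) {
          rows[[length(rows) + 1L]] <-
            data.frame(strand = strand, a0 = a0, b0 = b0, len = L,
                       mm = mm[b0 + 1L])
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(), target_start = integer(),
                      match_length = integer(), mismatches = integer()))
  }
  df <- do.call(rbind, rows)
  df$diag <- df$b0 - df$a0
  keep <- do.call(rbind, lapply(split(df, list(df$strand, df$diag),
                                      drop = TRUE), function(g) {
    g <- g[g$len == max(g$len), , drop = FALSE]
    g <- g[g$mm == min(g$mm), , drop = FALSE]
    g[which.min(g$b0), , drop = FALSE]
  }))
  out <- data.frame(strand = keep$strand, target_start = keep$b0,
                    match_length = keep$len, mismatches = keep$mm)
  out[order(out$strand, out$target_start), , drop = FALSE]
}

# Brute-force reimplementation of the consensus-annotation rule.
oracle_consensus <- function(member_ids, hits, e_max = 1e-5, min_frac = 0.05) {
  best <- 0L
  best_label <- "hyp"
  for (lb in sort(unique(hits$label))) {
    cnt <- length(unique(hits$protein_id[
      hits$label == lb & hits$e_value < e_max &
        hits$protein_id %in% member_ids]))
    if (cnt > best) {
      best <- cnt
      best_label <- lb
    }
  }
  need <- ceiling(min_frac * length(member_ids) - 1e-9)
  if (best > 0 && best >= need) best_label else "hyp"
}

# Brute-force 6-frame ORF scan (first ATG after each stop, through the next
# in-frame stop; N codons void the segment).
oracle_orfs <- function(seq, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else phagecontext::rev_comp(seq)
    for (frame in 0:2) {
      i <- frame + 1L
      seg_atg <- NA_integer_
      while (i + 2L <= L) {
        codon <- substr(s, i, i + 2L)
        if (grepl("N", codon)) {
          seg_atg <- NA_integer_
        } else if (codon %in% stops) {
          if (!is.na(seg_atg) && (i - seg_atg) / 3 >= min_aa) {
            a <- seg_atg - 1L
            b <- i + 2L
            if (strand == "+") {
              out[[length(out) + 1L]] <- c(a, b)
            } else {
              out[[length(out) + 1L]] <- c(L - b, L - a)
            }
          }
          seg_atg <- NA_integer_
        } else if (is.na(seg_atg) && codon == "ATG") {
          seg_atg <- i
        }
        i <- i + 3L
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- choose(sum(tab), 2)
  exp_a <- b * cc / n
  (a - exp_a) / ((b + cc) / 2 - exp_a)
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Plant a mutated substring of `spacer` into `target` (returns new target).
plant_protospacer <- function(target, spacer, n_mut) {
  chars <- strsplit(spacer, "")[[1]]
  if (n_mut > 0) {
    pos <- sample(length(chars), n_mut)
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  ins <- sample(nchar(target) - length(chars), 1)
  paste0(substr(target, 1, ins), paste(chars, collapse = ""),
         substr(target, ins + length(chars) + 1, nchar(target)))
}
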