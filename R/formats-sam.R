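# SAM support is deliberately minimal: the pipeline consumes POS, FLAG,
# CIGAR, SEQ length and an NM-style tag, with @SQ headers defining target
# lengths. Blocks are 0-based half-open target intervals; D extends the
# current block (deletions consume target), N splits it, I/S/H consume no
# target, P is unsupported.

parse_cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar)) {
    abort(paste0("malformed CIGAR: ", cigar))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = sub("^\\d+", "", toks)
  )
}

# CIGAR -> matrix of [start, end) target blocks, given 0-based start pos.
cigar_to_blocks <- function(cigar, pos0) {
  ops <- parse_cigar_ops(cigar)
  if (any(ops$op == "P")) abort(paste0("unsupported CIGAR op 'P' in: ", cigar))
  starts <- integer(0)
  ends <- integer(0)
  cur_start <- NA_integer_
  cur <- pos0
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- cur
      cur <- cur + len
    } else if (op == "N") {
      if (!is.na(cur_start)) {
        starts <- c(starts, cur_start)
        ends <- c(ends, cur)
        cur_start <- NA_integer_
      }
      cur <- cur + len
    }
    # I, S, H consume no target
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start)
    ends <- c(ends, cur)
  }
  cbind(start = starts, end = ends)
}

cigar_read_length <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

#' Read alignments from a SAM file
#'
#' Parses a restricted SAM dialect (see Details) into an alignment table.
#' Unmapped records are skipped. Mismatch counts come from the `NM:i:` tag;
#' records lacking the tag are treated as having 0 mismatches, with one
#' warning per file.
#'
#' @details Aligned blocks are derived from the CIGAR: `M`/`=`/`X` consume
#' read and target, `D` consumes target and extends the current block, `N`
#' consumes target and splits blocks, `I`/`S` consume read only, `H` is
#' ignored, `P` is an error. Read length is taken from SEQ when present,
#' otherwise reconstructed from the CIGAR.
#'
#' @param path path to a SAM file.
#' @param rna logical; mark records as RNA alignments.
#' @return a tibble with columns `read_id`, `target_id`, `target_start`
#'   (0-based), `read_length`, `mismatches`, `is_rna` and a list-column
#'   `blocks` of two-column `[start, end)` matrices. Target lengths from
#'   `@SQ` headers are attached as attribute `"targets"`.
#' @export
read_sam <- function(path, rna = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  targets <- tibble(
    target_id = stringr::str_match(sq, "SN:([^\\t]+)")[, 2],
    length = as.integer(stringr::str_match(sq, "LN:(\\d+)")[, 2])
  )
  if (length(body) == 0) {
    out <- tibble(read_id = character(), target_id = character(),
                  target_start = integer(), read_length = integer(),
                  mismatches = integer(), is_rna = logical(),
                  blocks = list())
    attr(out, "targets") <- targets
    return(out)
  }
  fields <- stringr::str_split_fixed(body, "\t", 12)
  flag <- as.integer(fields[, 2])
  mapped <- bitwAnd(flag, 4L) == 0L & fields[, 3] != "*"
  fields <- fields[mapped, , drop = FALSE]
  body <- body[mapped]
  nm <- stringr::str_match(body, "\\tNM:i:(\\d+)")[, 2]
  if (any(is.na(nm))) {
    warn(paste0(sum(is.na(nm)), " SAM record(s) lack an NM tag; ",
                "treating their mismatch count as 0"))
    nm[is.na(nm)] <- "0"
  }
  seqs <- fields[, 10]
  cigars <- fields[, 6]
  read_len <- ifelse(seqs == "*" | seqs == "",
                     vapply(cigars, cigar_read_length, integer(1)),
                     nchar(seqs))
  pos0 <- as.integer(fields[, 4]) - 1L
  blocks <- purrr::map2(cigars, pos0, cigar_to_blocks)
  out <- tibble(
    read_id = fields[, 1],
    target_id = fields[, 3],
    target_start = pos0,
    read_length = as.integer(read_len),
    mismatches = as.integer(nm),
    is_rna = rna,
    blocks = blocks
  )
  attr(out, "targets") <- targets
  out
}

#' Write alignments to a SAM file
#'
#' Indel-free writer for simulated alignments: the block widths of each
#' record must sum to its read length. Records with several blocks (reads
#' wrapping a circular origin) are emitted as one primary plus supplementary
#' lines with soft-clipped CIGARs; the full mismatch count is carried on the
#' primary line.
#'
#' @param alignments an alignment table as returned by [read_sam()] or
#'   [simulate_alignments()].
#' @param targets a genome table (or tibble with `target_id`/`genome_id` and
#'   lengths) used to emit `@SQ` headers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, targets, path) {
  if ("genome_id" %in% names(targets)) {
    tid <- targets$genome_id
    tlen <- nchar(targets$sequence)
  } else {
    tid <- targets$target_id
    tlen <- targets$length
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", tid, "\tLN:", tlen))
  recs <- purrr::pmap(alignments, function(read_id, target_start, read_length,
                                           mismatches, blocks, target_id, ...) {
    widths <- blocks[, "end"] - blocks[, "start"]
    if (sum(widths) != read_length) {
      abort(paste0("record ", read_id,
                   ": block widths must sum to read_length for SAM export"))
    }
    before <- cumsum(c(0L, widths))[seq_along(widths)]
    after <- read_length - before - widths
    cigar <- paste0(ifelse(before > 0, paste0(before, "S"), ""),
                    widths, "M",
                    ifelse(after > 0, paste0(after, "S"), ""))
    flag <- c(0L, rep(2048L, length(widths) - 1L))
    nm <- c(mismatches, rep(0L, length(widths) - 1L))
    paste(read_id, flag, target_id, blocks[, "start"] + 1L, 60L, cigar,
          "*", 0L, 0L, "*", "*", paste0("NM:i:", nm), sep = "\t")
  })
  writeLines(c(hdr, unlist(recs)), path)
  invisible(path)
}
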