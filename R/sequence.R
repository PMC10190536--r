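## Sequence primitives for the miRNA rewiring screen.
##
## All coordinates are 1-based on the transcript strand. Internally
## sequences are RNA (ACGU, uppercase); DNA input (T) is accepted and
## converted losslessly.

#' Normalize a nucleotide sequence to RNA letters
#'
#' Uppercases and converts T to U. Any residue outside ACGU afterwards is
#' an error: the rewiring screen has no meaningful interpretation for
#' ambiguity codes or gaps.
#'
#' @param seq character scalar, DNA or RNA letters.
#' @return character scalar over ACGU.
#' @export
normalize_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  bad <- gsub("[ACGU]", "", s)
  if (nzchar(bad)) {
    stop("sequence contains letters outside the ACGU/ACGT alphabet: '",
         substr(bad, 1L, 10L), "'")
  }
  s
}

## reverse complement over RNA letters
rc_rna <- function(s) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

comp_rna <- function(s) chartr("ACGU", "UGCA", s)

#' Find canonical miRNA seed-match sites on a 3'-UTR
#'
#' Scans every window of the UTR for the three canonical TargetScan site
#' types, defined by exact Watson–Crick complementarity to the miRNA seed
#' (positions 2–8, no wobble pairs):
#'
#' * **8mer**: reverse complement of miRNA positions 2–8 followed by an A
#'   opposite position 1;
#' * **7mer-m8**: reverse complement of positions 2–8, no A requirement;
#' * **7mer-A1**: reverse complement of positions 2–7 followed by an A.
#'
#' Where a longer match subsumes a shorter one at the same locus only the
#' strongest type is reported (8mer > 7mer-m8 > 7mer-A1).
#'
#' @param mirna mature miRNA sequence, 5'→3', at least 8 nt.
#' @param utr UTR sequence on the transcript strand, 5'→3'.
#' @return data.frame with columns `utr_start`, `utr_end` (1-based,
#'   inclusive) and `site_type`; zero rows when no site exists.
#' @examples
#' # let-7 family: seed 2-8 = GAGGUAG, 8mer target CUACCUCA
#' find_seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "GGGCUACCUCAGGG")
#' @export
find_seed_sites <- function(mirna, utr) {
  mirna <- normalize_rna(mirna)
  utr <- normalize_rna(utr)
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt")
  L <- nchar(utr)
  core <- rc_rna(substr(mirna, 2L, 7L))     # 6mer seed match
  m8 <- comp_rna(substr(mirna, 8L, 8L))     # base opposite position 8
  out <- list()
  if (L >= 6L) {
    for (q in seq_len(L - 5L)) {
      if (substr(utr, q, q + 5L) != core) next
      has_m8 <- q > 1L && substr(utr, q - 1L, q - 1L) == m8
      has_a1 <- q + 6L <= L && substr(utr, q + 6L, q + 6L) == "A"
      if (has_m8 && has_a1) {
        out[[length(out) + 1L]] <- c(q - 1L, q + 6L, "8mer")
      } else if (has_m8) {
        out[[length(out) + 1L]] <- c(q - 1L, q + 5L, "7mer-m8")
      } else if (has_a1) {
        out[[length(out) + 1L]] <- c(q, q + 6L, "7mer-A1")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(utr_start = integer(), utr_end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(utr_start = as.integer(m[, 1L]), utr_end = as.integer(m[, 2L]),
             site_type = m[, 3L], stringsAsFactors = FALSE)
}

#' Apply A-to-G edits to a transcript sequence
#'
#' In-silico A-to-I editing: inosine is read as guanosine, so each edited
#' position is replaced by G. Every position must hold an A on the
#' transcript strand — anything else indicates a strand or coordinate bug
#' upstream and is an error.
#'
#' @param utr sequence on the transcript strand.
#' @param edit_positions integer vector of 1-based offsets holding A.
#' @return edited sequence, same length, RNA letters.
#' @export
edit_sequence <- function(utr, edit_positions) {
  utr <- normalize_rna(utr)
  if (!length(edit_positions)) return(utr)
  edit_positions <- as.integer(edit_positions)
  if (any(is.na(edit_positions)) || any(edit_positions < 1L) ||
      any(edit_positions > nchar(utr))) {
    stop("edit positions out of sequence bounds")
  }
  ch <- strsplit(utr, "", fixed = TRUE)[[1L]]
  notA <- edit_positions[ch[edit_positions] != "A"]
  if (length(notA)) {
    stop("position ", notA[1L], " holds '", ch[notA[1L]],
         "', not A; refusing to edit (check strand/coordinates)")
  }
  ch[edit_positions] <- "G"
  paste(ch, collapse = "")
}

#' Classify miRNA seed-site gain/loss caused by editing sites on a UTR
#'
#' For each editing site and each miRNA, compares the canonical seed sites
#' of the unedited and the A-to-G-edited UTR, restricted to sites whose
#' window overlaps the edited position (distal sites elsewhere on the UTR
#' cannot masquerade as events). An interaction present only in the edited
#' sequence is a *gain*, one present only in the unedited sequence a
#' *loss*; unchanged loci produce no event.
#'
#' @param utr unedited UTR sequence (transcript strand).
#' @param des_positions named integer vector of 1-based UTR offsets of the
#'   editing sites; names are site ids.
#' @param mirnas named character vector of mature miRNA sequences.
#' @param gene_id optional gene id copied into the result.
#' @return data.frame with columns `site_id`, `utr_pos`, `mirna_id`,
#'   `class` ("gain"/"loss"), `gene_id`, `n_unedited_sites`,
#'   `n_edited_sites`.
#' @export
classify_rewiring <- function(utr, des_positions, mirnas, gene_id = NA_character_) {
  utr <- normalize_rna(utr)
  if (is.null(names(mirnas)) || anyNA(names(mirnas))) {
    stop("mirnas must be a named vector of sequences")
  }
  ids <- names(des_positions)
  if (is.null(ids)) ids <- paste0("pos", des_positions)
  rows <- list()
  for (i in seq_along(des_positions)) {
    pos <- as.integer(des_positions[[i]])
    edited <- edit_sequence(utr, pos)
    for (m in names(mirnas)) {
      s_un <- find_seed_sites(mirnas[[m]], utr)
      s_ed <- find_seed_sites(mirnas[[m]], edited)
      ov_un <- s_un[s_un$utr_start <= pos & s_un$utr_end >= pos, , drop = FALSE]
      ov_ed <- s_ed[s_ed$utr_start <= pos & s_ed$utr_end >= pos, , drop = FALSE]
      cls <- if (nrow(ov_un) == 0L && nrow(ov_ed) > 0L) "gain"
             else if (nrow(ov_un) > 0L && nrow(ov_ed) == 0L) "loss"
             else NA_character_
      if (!is.na(cls)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = ids[i], utr_pos = pos, mirna_id = m, class = cls,
          gene_id = gene_id, n_unedited_sites = nrow(ov_un),
          n_edited_sites = nrow(ov_ed), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(site_id = character(), utr_pos = integer(),
                      mirna_id = character(), class = character(),
                      gene_id = character(), n_unedited_sites = integer(),
                      n_edited_sites = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Extract flanking windows around editing sites for motif discovery
#'
#' Returns the ±`flank` bp window centred on each site (length
#' `2*flank + 1`), truncated with a warning where the site is within
#' `flank` of a contig end. The records are suitable as input for motif
#' tools such as MEME.
#'
#' @param sites data.frame with columns `site_id`, `contig`, `pos`
#'   (1-based position on the contig).
#' @param contigs named character vector of contig sequences.
#' @param flank nonnegative integer flank size (default 20).
#' @return named character vector of window sequences (names = site ids).
#' @export
extract_windows <- function(sites, contigs, flank = 20L) {
  stopifnot(all(c("site_id", "contig", "pos") %in% names(sites)),
            flank >= 0L)
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ctg <- contigs[[sites$contig[i]]]
    if (is.null(ctg)) stop("unknown contig '", sites$contig[i], "'")
    L <- nchar(ctg)
    pos <- sites$pos[i]
    if (is.na(pos) || pos < 1L || pos > L) {
      stop("site ", sites$site_id[i], " position ", pos,
           " outside contig bounds [1,", L, "]")
    }
    lo <- max(1L, pos - flank)
    hi <- min(L, pos + flank)
    if (lo > pos - flank || hi < pos + flank) {
      warning("window for site ", sites$site_id[i],
              " truncated at contig boundary")
    }
    out[i] <- substr(ctg, lo, hi)
  }
  names(out) <- sites$site_id
  out
}
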