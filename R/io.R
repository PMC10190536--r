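## Readers and writers for every file the pipeline touches. All readers
## validate and reject rather than coerce; every writer/reader pair
## round-trips exactly on valid data.

REGION_LEVELS <- c("3'-UTR", "5'-UTR", "exonic", "intronic", "intergenic",
                   "ncRNA")

#' Read an editing-level matrix
#'
#' TSV with a header row of sample ids and a first column of site ids.
#' Empty cells and "NA" encode missing values. Values must lie in
#' \[0,1\]; a value outside the range is rejected naming the offending
#' site and sample, as are duplicate site or sample ids.
#'
#' @param path file path.
#' @return numeric matrix, sites in rows (rownames), samples in columns
#'   (colnames), `NA` for missing.
#' @export
read_editing_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("editing matrix needs a site-id column and >=1 sample")
  sites <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(sites)) {
    stop("duplicate site id: ", sites[duplicated(sites)][1L])
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1L])
  }
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(samples),
              dimnames = list(sites, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad_num <- which(!is.na(raw) & is.na(val))
    if (length(bad_num)) {
      stop("non-numeric editing value '", raw[bad_num[1L]], "' at site ",
           sites[bad_num[1L]], ", sample ", samples[j])
    }
    bad <- which(!is.na(val) & (val < 0 | val > 1))
    if (length(bad)) {
      stop("editing value ", val[bad[1L]], " outside [0,1] at site ",
           sites[bad[1L]], ", sample ", samples[j])
    }
    m[, j] <- val
  }
  m
}

#' Write an editing-level matrix
#'
#' Inverse of [read_editing_matrix()]; missing values become empty cells.
#'
#' @param profile numeric matrix with site rownames and sample colnames.
#' @param path output path.
#' @export
write_editing_matrix <- function(profile, path) {
  stopifnot(is.matrix(profile), !is.null(rownames(profile)),
            !is.null(colnames(profile)))
  rng <- range(profile, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("editing values outside [0,1]")
  df <- data.frame(site_id = rownames(profile), profile,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a site annotation table
#'
#' TSV with columns `site_id`, `chrom`, `pos` (1-based), `strand` (+/-),
#' `gene_id` (empty for intergenic sites) and `region` from the closed
#' vocabulary 3'-UTR, 5'-UTR, exonic, intronic, intergenic, ncRNA.
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  need <- c("site_id", "chrom", "pos", "strand", "gene_id", "region")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  df$pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) stop("invalid position at line ", bad[1L] + 1L)
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", bad[1L] + 1L)
  bad <- which(!df$region %in% REGION_LEVELS)
  if (length(bad)) {
    stop("region '", df$region[bad[1L]], "' at line ", bad[1L] + 1L,
         " not in the closed vocabulary (",
         paste(REGION_LEVELS, collapse = ", "), ")")
  }
  bad <- which(df$region == "intergenic" & !is.na(df$gene_id))
  if (length(bad)) {
    stop("intergenic site ", df$site_id[bad[1L]], " must not carry a gene_id")
  }
  if (anyDuplicated(df$site_id)) {
    stop("duplicate site id in annotation: ",
         df$site_id[duplicated(df$site_id)][1L])
  }
  df
}

#' @rdname read_annotation
#' @param annotation annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Export site positions as BED
#'
#' Converts the 1-based annotation coordinates to 0-based half-open BED
#' intervals explicitly.
#'
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param path output path.
#' @export
write_bed <- function(annotation, path) {
  bed <- data.frame(chrom = annotation$chrom,
                    start = annotation$pos - 1L,
                    end = annotation$pos,
                    name = annotation$site_id,
                    score = 0L,
                    strand = annotation$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' DNA or RNA letters are accepted; U is mapped to T on write and the
#' reverse mapping is applied by the sequence layer, so the conversion is
#' lossless. Duplicate record ids are an error.
#'
#' @param path FASTA path.
#' @return named character vector of sequences (uppercase).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  stats::setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences; RNA letters are
#'   written as DNA (U -> T).
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  dna <- chartr("Uu", "Tt", seqs)
  ss <- Biostrings::BStringSet(dna)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an expression table (features x samples, FPKM-like)
#'
#' @param path TSV with a feature-id first column and sample-id header.
#' @return numeric matrix, features in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature id: ",
                               ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (anyNA(m)) stop("expression table contains missing values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression at feature ", ids[bad[1L]])
  }
  m
}

#' @rdname read_expression
#' @param expr numeric matrix with feature rownames and sample colnames.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time` (> 0), `event` (0/1).
#'
#' @param path file path.
#' @return data.frame with the three validated columns.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  }
  df$sample <- as.character(df$sample)
  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad)) stop("non-positive survival time at line ", bad[1L] + 1L)
  bad <- which(!df$event %in% c(0L, 1L))
  if (length(bad)) stop("event must be 0 or 1 at line ", bad[1L] + 1L)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample in survival table: ",
         df$sample[duplicated(df$sample)][1L])
  }
  df[, need]
}

#' @rdname read_survival
#' @param surv survival data.frame.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug-response table
#'
#' TSV with columns `sample`, `cancer`, `drug`, `response_label` (free
#' text; see [label_tumor_samples()] for the labels that are used).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_response <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("sample", "cancer", "drug", "response_label")
  if (!all(need %in% names(df))) {
    stop("response table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_response
#' @param response response data.frame.
#' @export
write_response <- function(response, path) {
  utils::write.table(response, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## generic TSV writer used by pipeline outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
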