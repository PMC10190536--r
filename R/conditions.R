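## Derivation of analysis conditions from clinical response labels and
## cell-line ln(IC50) values.

#' Construct a condition
#'
#' A condition is one drug in one cancer type together with its labeled
#' resistant and sensitive sample sets. The two sets must be disjoint and
#' nonempty.
#'
#' @param cancer,drug labels.
#' @param resistant,sensitive character vectors of sample ids.
#' @return object of class `condition`.
#' @export
condition <- function(cancer, drug, resistant, sensitive) {
  resistant <- unique(as.character(resistant))
  sensitive <- unique(as.character(sensitive))
  if (!length(resistant) || !length(sensitive)) {
    stop("a condition needs nonempty resistant and sensitive sets")
  }
  if (length(intersect(resistant, sensitive))) {
    stop("resistant and sensitive sample sets overlap")
  }
  structure(list(cancer = cancer, drug = drug, resistant = resistant,
                 sensitive = sensitive),
            class = "condition")
}

#' @export
print.condition <- function(x, ...) {
  cat(sprintf("<condition> %s-%s: %d resistant, %d sensitive\n",
              x$cancer, x$drug, length(x$resistant), length(x$sensitive)))
  invisible(x)
}

#' Label tumor samples from clinical response annotations
#'
#' Samples annotated "Progressive Disease" are labeled resistant and
#' "Complete Response" sensitive; samples with any other annotation
#' (e.g. "Partial Response", "Stable Disease") are excluded and counted
#' in a message.
#'
#' @param response data.frame with columns `sample`, `cancer`, `drug`,
#'   `response_label`.
#' @return data.frame `sample`, `cancer`, `drug`, `label`
#'   (resistant/sensitive); zero rows for an empty input.
#' @export
label_tumor_samples <- function(response) {
  need <- c("sample", "cancer", "drug", "response_label")
  stopifnot(all(need %in% names(response)))
  map <- c("Progressive Disease" = "resistant",
           "Complete Response" = "sensitive")
  lab <- map[response$response_label]
  dropped <- sum(is.na(lab))
  if (dropped > 0L) {
    message(dropped, " sample record(s) with other response labels excluded")
  }
  keep <- !is.na(lab)
  data.frame(sample = as.character(response$sample[keep]),
             cancer = as.character(response$cancer[keep]),
             drug = as.character(response$drug[keep]),
             label = unname(lab[keep]), stringsAsFactors = FALSE)
}

#' Build conditions from labeled samples
#'
#' One condition per (cancer, drug) pair having at least `min_per_group`
#' resistant and sensitive samples; pairs below the threshold are dropped
#' with a message. The result does not depend on the row order of the
#' input.
#'
#' @param labels output of [label_tumor_samples()].
#' @param min_per_group minimum samples per group (default 3).
#' @return named list of [condition()] objects ("cancer-drug" names),
#'   ordered by name.
#' @export
build_conditions <- function(labels, min_per_group = 3L) {
  if (!nrow(labels)) return(list())
  key <- paste(labels$cancer, labels$drug, sep = "-")
  out <- list()
  for (k in sort(unique(key))) {
    sub <- labels[key == k, , drop = FALSE]
    res <- sort(unique(sub$sample[sub$label == "resistant"]))
    sen <- sort(unique(sub$sample[sub$label == "sensitive"]))
    if (length(res) >= min_per_group && length(sen) >= min_per_group) {
      out[[k]] <- condition(sub$cancer[1L], sub$drug[1L], res, sen)
    } else {
      message("condition ", k, " dropped: ", length(res), " resistant / ",
              length(sen), " sensitive (< ", min_per_group, " per group)")
    }
  }
  out
}

#' Label cell lines from ln(IC50) values by z-score
#'
#' Within each compound, ln(IC50) values are standardized
#' (z = (x - mean)/sd, sample sd with denominator n-1). A cell line is
#' resistant when z > `z_cut`, sensitive when z < -`z_cut` (strict
#' inequalities), and intermediate otherwise — intermediate lines are kept
#' in the table but are not used in downstream analyses.
#'
#' @param ic50 data.frame with columns `cell_line`, `compound`, `ln_ic50`.
#' @param z_cut z-score threshold (default 0.8).
#' @return the input with added columns `z` and `label`.
#' @export
label_cell_lines <- function(ic50, z_cut = 0.8) {
  need <- c("cell_line", "compound", "ln_ic50")
  stopifnot(all(need %in% names(ic50)))
  out <- ic50
  out$z <- NA_real_
  out$label <- NA_character_
  for (cp in unique(ic50$compound)) {
    idx <- which(ic50$compound == cp)
    if (length(idx) < 2L) stop("compound ", cp, " has fewer than 2 cell lines")
    x <- ic50$ln_ic50[idx]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("zero ln(IC50) variance for compound ", cp)
    }
    z <- (x - mean(x)) / s
    out$z[idx] <- z
    out$label[idx] <- ifelse(z > z_cut, "resistant",
                             ifelse(z < -z_cut, "sensitive", "intermediate"))
  }
  out
}
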