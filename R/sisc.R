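#' Classification count records
#'
#' A tidy container for catFISH tallies: per animal/region counts of cells
#' classified negative (`neg`), nuclear Arc-positive (`nuc`), cytoplasmic
#' Arc-positive (`cyt`), and double (`dob`). `total = neg + nuc + cyt +
#' dob` always.
#'
#' @param neg,nuc,cyt,dob non-negative integer counts (vectorized).
#' @param animal_id,region,condition,pretreatment optional metadata;
#'   `region` is typically `"CA1"` or `"CA3"`, `condition` one of `"AA"`,
#'   `"AA'"`, `"AB"`, `"CC"`, `pretreatment` one of `"IC"`, `"SC"`, `"WM"`.
#' @return A `data.frame` of class `cell_counts`.
#' @examples
#' cell_counts(neg = 50, nuc = 10, cyt = 15, dob = 25)
#' @export
cell_counts <- function(neg, nuc, cyt, dob, animal_id = NA_character_,
                        region = NA_character_, condition = NA_character_,
                        pretreatment = NA_character_) {
  counts <- data.frame(animal_id = animal_id, region = region,
                       condition = condition, pretreatment = pretreatment,
                       neg = as.integer(neg), nuc = as.integer(nuc),
                       cyt = as.integer(cyt), dob = as.integer(dob))
  if (any(counts$neg < 0 | counts$nuc < 0 | counts$cyt < 0 | counts$dob < 0))
    stop("counts must be non-negative", call. = FALSE)
  counts$total <- counts$neg + counts$nuc + counts$cyt + counts$dob
  class(counts) <- c("cell_counts", "data.frame")
  counts
}

#' Epoch activation proportions
#'
#' Cytoplasmic Arc staining marks epoch-1 activity and intranuclear foci
#' mark epoch-2 activity, so
#' `epoch1 = (cyt + dob) / total` and `epoch2 = (nuc + dob) / total`.
#'
#' @param counts a [cell_counts()] data frame (any number of rows).
#' @return A `data.frame` with columns `epoch1`, `epoch2`.
#' @examples
#' epoch_proportions(cell_counts(neg = 49, nuc = 21, cyt = 21, dob = 9))
#' @export
epoch_proportions <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (any(counts$total == 0))
    stop("cannot compute epoch proportions for a record with total = 0",
         call. = FALSE)
  data.frame(epoch1 = (counts$cyt + counts$dob) / counts$total,
             epoch2 = (counts$nuc + counts$dob) / counts$total)
}

#' Similarity score (SiSc)
#'
#' The similarity score measures the overlap between the neuronal
#' ensembles recruited in two behavioral epochs, normalizing the excess of
#' doubly active cells over the independence expectation by the maximum
#' possible excess:
#' \deqn{\mathrm{SiSc} = \frac{\mathrm{dob}/\mathrm{total} - E_1 E_2}
#'                            {\min(E_1, E_2) - E_1 E_2}.}
#' A value near 1 indicates a single population faithfully reactivated in
#' both epochs; a value near 0 indicates two statistically independent
#' populations. Negative values (fewer doubles than chance) are reported
#' as-is, not clipped.
#'
#' When `least_epoch == p_e1e2` (e.g. an epoch with zero or complete
#' activation) the score is undefined: `sisc` is `NA` and the
#' `undefined` flag is set, never a silent number.
#'
#' @param counts a [cell_counts()] data frame (vectorized over rows).
#' @return A `data.frame` with the metadata columns of `counts` plus
#'   `epoch1`, `epoch2`, `least_epoch`, `p_e1e2` (chance double
#'   proportion), `diff_e1e2` (observed minus chance), `sisc`, and
#'   `undefined`.
#' @examples
#' similarity_score(cell_counts(neg = 50, nuc = 10, cyt = 15, dob = 25))$sisc
#' @export
similarity_score <- function(counts) {
  ep <- epoch_proportions(counts)
  least <- pmin(ep$epoch1, ep$epoch2)
  p12 <- ep$epoch1 * ep$epoch2
  diff12 <- counts$dob / counts$total - p12
  denom <- least - p12
  undefined <- abs(denom) < .Machine$double.eps^0.5
  sisc <- ifelse(undefined, NA_real_, diff12 / denom)
  meta <- intersect(c("animal_id", "region", "condition", "pretreatment"),
                    names(counts))
  out <- cbind(as.data.frame(counts)[, meta, drop = FALSE],
               data.frame(epoch1 = ep$epoch1, epoch2 = ep$epoch2,
                          least_epoch = least, p_e1e2 = p12,
                          diff_e1e2 = diff12, sisc = sisc,
                          undefined = undefined))
  rownames(out) <- NULL
  out
}

#' Similarity-score table over animals and regions
#'
#' Computes one SiSc per (animal, region, condition, pretreatment) key
#' from pooled per-animal counts. Cage-control (`CC`) animals are excluded
#' from the score table, since their single-epoch design makes ensemble
#' overlap meaningless. Records with an undefined score are retained with
#' `sisc = NA` and flagged, so callers can count exclusions.
#'
#' @param counts a [cell_counts()] data frame, one row per key.
#' @param exclude_conditions conditions dropped from the table
#'   (default `"CC"`).
#' @return A `data.frame` as from [similarity_score()], one row per key.
#' @export
sisc_table <- function(counts, exclude_conditions = "CC") {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0) return(similarity_score(counts))
  keep <- !(counts$condition %in% exclude_conditions)
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts)) {
    key <- paste(counts$animal_id, counts$region, counts$condition,
                 counts$pretreatment, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (animal, region, condition, pretreatment) keys; ",
           "pool counts per animal/region before scoring", call. = FALSE)
  }
  similarity_score(counts)
}
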