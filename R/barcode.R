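#' Parse TCGA sample barcodes
#'
#' Decomposes TCGA aliquot barcodes (e.g. \code{"TCGA-A1-A0SB-01A-11R-A144-07"})
#' into their dash-separated fields: project, tissue source site (TSS),
#' participant, sample type + vial, and an optional portion/analyte/plate/center
#' remainder. The two-digit sample-type code classifies a sample as tumor
#' (codes 1-9) or normal (codes 10-19); codes 20-29 are controls.
#'
#' The \code{sample_key} column (\code{participant_id} plus the two-digit
#' sample-type code) is the identity used throughout the package: it collapses
#' replicate vials and aliquots of the same physical sample so that, e.g., two
#' aliquots of one tumor count once in a mutation frequency.
#'
#' @param x character vector of barcodes. Each must have at least four
#'   dash-separated fields, the fourth starting with two digits in 01-29.
#' @return a data.frame of class \code{"tcga_barcodes"} with one row per input
#'   and columns \code{raw}, \code{project}, \code{tss}, \code{participant},
#'   \code{sample_type} (integer), \code{vial}, \code{remainder},
#'   \code{participant_id}, \code{sample_key}, \code{is_tumor},
#'   \code{is_normal}.
#' @examples
#' b <- parse_barcode("TCGA-A1-A0SB-01A-11R-A144-07")
#' b$participant_id  # "TCGA-A1-A0SB"
#' b$is_tumor        # TRUE
#' @export
parse_barcode <- function(x) {
  if (!is.character(x)) stop("barcodes must be a character vector")
  if (length(x) == 0L) {
    return(empty_barcode_frame())
  }
  fields <- strsplit(x, "-", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed barcode '", x[which(nf < 4L)[1L]],
         "': missing sample-type field (need >= 4 dash-separated fields)")
  }
  f <- function(i) vapply(fields, `[[`, character(1L), i)
  project <- f(1L)
  tss <- f(2L)
  participant <- f(3L)
  st_field <- f(4L)

  bad <- !grepl("^[0-9]{2}", st_field)
  if (any(bad)) {
    stop("malformed barcode '", x[which(bad)[1L]],
         "': sample-type field '", st_field[which(bad)[1L]],
         "' does not start with two digits")
  }
  bad <- nchar(tss) != 2L
  if (any(bad)) {
    stop("malformed barcode '", x[which(bad)[1L]],
         "': tissue source site '", tss[which(bad)[1L]], "' is not 2 characters")
  }
  bad <- nchar(participant) != 4L
  if (any(bad)) {
    stop("malformed barcode '", x[which(bad)[1L]],
         "': participant code '", participant[which(bad)[1L]],
         "' is not 4 characters")
  }
  sample_type <- as.integer(substr(st_field, 1L, 2L))
  bad <- sample_type < 1L | sample_type > 29L
  if (any(bad)) {
    stop("malformed barcode '", x[which(bad)[1L]],
         "': sample-type code ", sample_type[which(bad)[1L]],
         " outside 01-29")
  }
  vial <- ifelse(nchar(st_field) >= 3L, substr(st_field, 3L, 3L), NA_character_)
  remainder <- vapply(fields, function(ff) {
    if (length(ff) > 4L) paste(ff[-(1:4)], collapse = "-") else NA_character_
  }, character(1L))
  participant_id <- paste(project, tss, participant, sep = "-")
  out <- data.frame(
    raw = x,
    project = project,
    tss = tss,
    participant = participant,
    sample_type = sample_type,
    vial = vial,
    remainder = remainder,
    participant_id = participant_id,
    sample_key = paste0(participant_id, "-", sprintf("%02d", sample_type)),
    is_tumor = sample_type >= 1L & sample_type <= 9L,
    is_normal = sample_type >= 10L & sample_type <= 19L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("tcga_barcodes", "data.frame")
  out
}

empty_barcode_frame <- function() {
  out <- data.frame(
    raw = character(0L), project = character(0L), tss = character(0L),
    participant = character(0L), sample_type = integer(0L),
    vial = character(0L), remainder = character(0L),
    participant_id = character(0L), sample_key = character(0L),
    is_tumor = logical(0L), is_normal = logical(0L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("tcga_barcodes", "data.frame")
  out
}

# TRUE for barcodes that parse_barcode() accepts, without raising.
barcode_is_valid <- function(x) {
  vapply(x, function(b) {
    !inherits(try(parse_barcode(b), silent = TRUE), "try-error")
  }, logical(1L), USE.NAMES = FALSE)
}
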