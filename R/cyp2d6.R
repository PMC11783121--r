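#' Default per-allele CYP2D6 activity values
#'
#' Continuous activity scale on which a fully functional \code{*1/*1}
#' diplotype scores exactly 1.0 (so each normal-function allele contributes
#' 0.5). Decreased-function alleles contribute less, null alleles zero, and a
#' copy-number suffix (\code{"*1x2"}) multiplies the base value. This scale is
#' deliberately distinct from the CPIC 0-3 activity score.
#'
#' The table is a plain named numeric vector so users can substitute their
#' own scale (e.g. via the \code{alleles} section of [load_config()]).
#'
#' @return named numeric vector mapping star alleles to activity values.
#' @examples
#' default_allele_table()[["*1"]]
#' @export
default_allele_table <- function() {
  c("*1" = 0.5, "*2" = 0.5, "*35" = 0.5,
    "*9" = 0.3, "*10" = 0.25, "*17" = 0.25, "*41" = 0.25,
    "*3" = 0, "*4" = 0, "*5" = 0, "*6" = 0)
}

# value of one allele string, honouring an "xN" copy-number suffix
allele_value <- function(allele, table) {
  m <- regexec("^(\\*[0-9A-Za-z.]+?)(?:x([0-9]+))?$", allele)
  parts <- regmatches(allele, m)[[1]]
  if (length(parts) == 0) {
    stop_domain("malformed allele string: '", allele, "'")
  }
  base <- parts[2]
  if (!base %in% names(table)) {
    stop_domain("unknown CYP2D6 allele '", base, "' (not in activity table)")
  }
  mult <- if (parts[3] == "") 1 else as.numeric(parts[3])
  unname(table[base]) * mult
}

#' Split diplotype strings into their two alleles
#'
#' @param diplotype character vector of slash-separated diplotypes, e.g.
#'   \code{"*1/*4"} or \code{"*1x2/*4"}.
#' @return a 2-column character matrix (allele_a, allele_b).
#' @export
parse_diplotype <- function(diplotype) {
  parts <- strsplit(as.character(diplotype), "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop_domain("diplotype must be two '/'-separated alleles; got: '",
                diplotype[bad][1], "'")
  }
  matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("allele_a", "allele_b")))
}

#' CYP2D6 activity score of a diplotype
#'
#' Sum of the two per-allele activity values; symmetric in allele order and
#' deterministic. \code{*1/*1} scores 1.0 by construction of the default
#' table.
#'
#' @param diplotype character vector of diplotype strings (\code{"*1/*4"}).
#' @param table named numeric allele-activity vector, see
#'   [default_allele_table()].
#' @return numeric vector of activity scores (typical range 0-1.5).
#' @examples
#' activity_score("*1/*1") # 1.0
#' activity_score("*1/*9") # 0.8
#' @export
activity_score <- function(diplotype, table = default_allele_table()) {
  if (any(!is.finite(table)) || any(table < 0)) {
    stop_domain("allele activity values must be finite and >= 0")
  }
  al <- parse_diplotype(diplotype)
  vapply(seq_len(nrow(al)), function(i) {
    allele_value(al[i, 1], table) + allele_value(al[i, 2], table)
  }, numeric(1))
}

#' The five CYP2D6 activity bins
#'
#' Left-open, right-closed intervals partitioning (0, 1.5]; a score of
#' exactly 0 belongs to the lowest bin (the "activity <= 0.3" group).
#'
#' @return data frame with columns `label`, `lower`, `upper`.
#' @export
activity_bins <- function() {
  data.frame(
    label = c("0.0-0.30", "0.30-0.60", "0.60-0.75", "0.75-0.90", "0.90-1.5"),
    lower = c(0, 0.30, 0.60, 0.75, 0.90),
    upper = c(0.30, 0.60, 0.75, 0.90, 1.5),
    stringsAsFactors = FALSE
  )
}

#' Assign activity scores to activity bins
#'
#' @param score numeric vector of activity scores (>= 0). Scores above 1.5
#'   are assigned to the top bin with a warning (the scale tops out at 1.5).
#' @return factor with the five bin labels of [activity_bins()].
#' @examples
#' assign_bin(c(0, 0.30, 0.68, 0.75 + 1e-9))
#' @export
assign_bin <- function(score) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop_domain("activity score must be finite and >= 0")
  }
  bins <- activity_bins()
  if (any(score > bins$upper[nrow(bins)])) {
    warning("activity score above 1.5: assigned to the top bin", call. = FALSE)
    score <- pmin(score, bins$upper[nrow(bins)])
  }
  cut(score, breaks = c(bins$lower, 1.5), labels = bins$label,
      include.lowest = TRUE, right = TRUE)
}
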