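# Five-class categorization of receptor mutations by kinase-domain
# location and curated oncogenicity, and the ordered per-line score used
# as a mutation-status predictor of inhibitor sensitivity.
#
# Class I is the superset "any protein-changing mutation"; classes II-V
# cross location (outside/inside the kinase-domain interval) with the
# oncogenic annotation: II = outside/not oncogenic, III = outside/oncogenic,
# IV = inside/not oncogenic, V = inside/oncogenic. Canonical activating
# variants such as L858R, S768I, L861Q and G719S are class V.

#' Kinase-domain residue interval
#'
#' The "kinase domain" used for mutation classing is a configurable residue
#' interval; the default 688-875 approximates exons 18-21 of EGFR.
#'
#' @param start,end inclusive residue bounds, `start <= end`.
#' @return integer vector `c(start, end)` of class `domain_interval`.
#' @export
kinase_domain <- function(start = 688, end = 875) {
  stopifnot(start >= 1, start <= end)
  structure(c(start = as.integer(start), end = as.integer(end)),
            class = "domain_interval")
}

#' Default ordinal mutation-class mapping
#'
#' Converts class labels into an ordered score aligned with oncogenic
#' potential: none=0 < II=1 < IV=2 < III=3 < V=4 (annotated oncogenicity
#' ranks above kinase-domain location).
#'
#' @return named numeric vector.
#' @export
default_class_mapping <- function() {
  c(none = 0, II = 1, IV = 2, III = 3, V = 4)
}

#' Parse the residue position from a protein change
#'
#' Extracts the first integer from strings such as `"L858R"` or
#' `"p.G719S"`; `NA` when no residue is parseable.
#'
#' @param protein_change character vector.
#' @return integer vector.
#' @export
parse_residue <- function(protein_change) {
  m <- regmatches(protein_change, regexpr("[0-9]+", protein_change))
  out <- rep(NA_integer_, length(protein_change))
  out[regexpr("[0-9]+", protein_change) > 0] <- as.integer(m)
  out
}

#' Classify mutation records into classes II-V
#'
#' @param mutations data frame with columns `cell_line`, `gene`,
#'   `protein_change`, `oncogenic` (logical).
#' @param domain a [kinase_domain()] interval.
#' @return the input with added columns `residue`, `class` (`"II".."V"` or
#'   `NA` for unparseable records) and `unparsed` (logical). Unparseable
#'   records are reported via a warning, never dropped.
#' @export
classify_mutations <- function(mutations, domain = kinase_domain()) {
  stopifnot(all(c("cell_line", "protein_change", "oncogenic") %in%
                  colnames(mutations)),
            inherits(domain, "domain_interval"))
  res <- parse_residue(mutations$protein_change)
  inside <- !is.na(res) & res >= domain[["start"]] & res <= domain[["end"]]
  onc <- as.logical(mutations$oncogenic)
  cls <- ifelse(inside & onc, "V",
                ifelse(inside & !onc, "IV",
                       ifelse(!inside & onc, "III", "II")))
  cls[is.na(res)] <- NA_character_
  unparsed <- is.na(res)
  if (any(unparsed)) {
    warning(sum(unparsed), " mutation record(s) with unparseable residue ",
            "routed to the unparsed report", call. = FALSE)
  }
  out <- mutations
  out$residue <- res
  out$class <- cls
  out$unparsed <- unparsed
  out
}

#' Single-record mutation classification
#'
#' @param protein_change protein change string with a parseable residue.
#' @param oncogenic logical oncogenicity annotation.
#' @param domain a [kinase_domain()].
#' @return one of `"II"`, `"III"`, `"IV"`, `"V"`.
#' @export
classify_mutation <- function(protein_change, oncogenic,
                              domain = kinase_domain()) {
  res <- parse_residue(protein_change)
  if (is.na(res)) stop("unparseable protein change: ", protein_change)
  df <- classify_mutations(
    data.frame(cell_line = "x", gene = "x", protein_change = protein_change,
               oncogenic = oncogenic),
    domain
  )
  df$class
}

#' Collapse a line's records to one class label
#'
#' A line with no records is `"none"`; otherwise the record class with the
#' highest ordinal score under `mapping` wins (default precedence
#' V > III > IV > II).
#'
#' @param classes character vector of record classes for one line (possibly
#'   empty; `NA` unparsed records are ignored).
#' @param mapping ordinal mapping, see [default_class_mapping()].
#' @return single class label.
#' @export
classify_cell_line <- function(classes, mapping = default_class_mapping()) {
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0) return("none")
  bad <- setdiff(classes, names(mapping))
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  classes[which.max(mapping[classes])]
}

#' Per-line class labels for a whole panel
#'
#' @param mutations classified mutation table ([classify_mutations()] output
#'   or raw table, classified on the fly).
#' @param lines all panel cell lines (lines without records become `"none"`).
#' @param domain a [kinase_domain()].
#' @param mapping ordinal mapping.
#' @return named character vector of class labels over `lines`.
#' @export
cell_line_classes <- function(mutations, lines, domain = kinase_domain(),
                              mapping = default_class_mapping()) {
  if (!"class" %in% colnames(mutations)) {
    mutations <- classify_mutations(mutations, domain)
  }
  by_line <- split(mutations$class, mutations$cell_line)
  out <- stats::setNames(rep("none", length(lines)), lines)
  hit <- intersect(names(by_line), lines)
  out[hit] <- vapply(by_line[hit], classify_cell_line, character(1),
                     mapping = mapping)
  out
}

#' Ordinal mutation score
#'
#' @param class_label class label(s) (`"none"`, `"II".."V"`).
#' @param mapping ordinal mapping; must assign a distinct rank to each label.
#' @return numeric score(s).
#' @export
mutation_score <- function(class_label, mapping = default_class_mapping()) {
  stopifnot(!anyDuplicated(mapping))
  bad <- setdiff(unique(class_label), names(mapping))
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  unname(mapping[class_label])
}

#' Per-class association between mutation class and drug response
#'
#' For each class II-V present, compares the AUC distribution of lines in
#' that class against wild-type (`"none"`) lines with a two-sample K-S
#' test. Classes with fewer than `min_n` lines are skipped with a reason.
#'
#' @param auc named per-line AUC vector.
#' @param line_classes named per-line class labels ([cell_line_classes()]).
#' @param min_n minimum lines per class (default 2).
#' @return data frame with columns `class`, `n`, `n_wt`, `D`, `p`, `skipped`.
#' @export
class_auc_association <- function(auc, line_classes, min_n = 2) {
  common <- intersect(names(auc), names(line_classes))
  auc <- auc[common]
  cls <- line_classes[common]
  wt <- auc[cls == "none"]
  if (length(wt) < min_n) stop("fewer than ", min_n, " wild-type lines")
  classes <- intersect(c("II", "III", "IV", "V"), unique(cls))
  rows <- lapply(classes, function(cc) {
    x <- auc[cls == cc]
    if (length(x) < min_n) {
      message("class ", cc, " skipped: only ", length(x), " line(s)")
      data.frame(class = cc, n = length(x), n_wt = length(wt),
                 D = NA_real_, p = NA_real_, skipped = TRUE)
    } else {
      kt <- ks_test(x, wt)
      data.frame(class = cc, n = length(x), n_wt = length(wt),
                 D = kt$D, p = kt$p, skipped = FALSE)
    }
  })
  do.call(rbind, rows)
}
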