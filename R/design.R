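#' Build a design matrix from sample metadata
#'
#' Expands a factor specification into a treatment-coded (dummy) design
#' matrix. Character columns become factors with alphabetically first level
#' as reference; columns that are already factors keep their level order, so
#' simulated data keep `control`/`vehicle` as reference. The design must be
#' full column rank.
#'
#' @param samples Sample tibble (`sample_id` + factors).
#' @param design A formula (`~ stress * treatment`) or the equivalent string
#'   (`"stress*treatment"`).
#' @return Numeric samples-by-coefficients matrix with sample-id rownames and
#'   a `formula` attribute.
#' @export
build_design <- function(samples, design) {
  if (is.character(design)) design <- as.formula(paste("~", design))
  if (!inherits(design, "formula")) abort("`design` must be a formula or string.")
  df <- as.data.frame(samples)
  for (v in all.vars(design)) {
    if (!v %in% names(df)) abort(sprintf("Design factor `%s` missing from samples.", v))
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]]) # alphabetical reference
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  X <- model.matrix(design, data = df)
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is not full column rank (confounded or empty levels).")
  }
  rownames(X) <- df$sample_id
  attr(X, "formula") <- design
  X
}

as_design <- function(design, samples) {
  if (is.matrix(design)) {
    if (ncol(design) > 0 && qr(design)$rank < ncol(design)) {
      abort("Design matrix is not full column rank.")
    }
    return(design)
  }
  build_design(samples, design)
}
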