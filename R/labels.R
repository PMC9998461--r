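#' Diagnosis classes
#'
#' Dysplasia grades form an ordered scale `NNeo (1) < LSIL (2) < HSIL (3)`;
#' non-representative slides (no exocervical squamous epithelium) carry the
#' unordered sentinel label `"OTHERS"`.
#'
#' @format `cg_classes()` returns the three ordinal class names in severity
#'   order; `cg_all_classes()` appends `"OTHERS"`.
#' @export
cg_classes <- function() c("NNeo", "LSIL", "HSIL")

#' @rdname cg_classes
#' @export
cg_all_classes <- function() c(cg_classes(), "OTHERS")

#' Convert between class names and ordinal codes
#'
#' @param x class names (`"NNeo"`, `"LSIL"`, `"HSIL"`) or integer codes 1..3.
#' @return `ordinal_label()` returns integer codes; `label_name()` names.
#'   `"OTHERS"` maps to `NA` because it has no rank on the severity scale.
#' @export
ordinal_label <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(x %in% 1:3 | is.na(x)))
    return(as.integer(x))
  }
  out <- match(as.character(x), cg_classes())
  bad <- !is.na(x) & is.na(out) & as.character(x) != "OTHERS"
  if (any(bad)) stop("unknown class label: ", paste(unique(x[bad]), collapse = ", "))
  as.integer(out)
}

#' @rdname ordinal_label
#' @export
label_name <- function(x) {
  if (is.character(x)) return(x)
  ifelse(is.na(x), "OTHERS", cg_classes()[x])
}
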