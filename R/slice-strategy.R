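## Slice-selection strategies for multi-slice cases: SINGLE represents a
## nodule by its middle slice; ALL uses every member slice for training and
## aggregates test-slice decisions by majority vote.

#' Build a case record from prepared slices
#'
#' @param case_id Identifier.
#' @param label `"benign"` or `"malignant"`.
#' @param slices List of `roi_sample` objects, ordered by `slice_index`.
#' @param thickness Slice thickness in mm (`NA` for single-slice 2-D data).
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, label, slices, thickness = NA_real_) {
  if (!length(slices)) stop_input("a case needs at least one slice")
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  slices <- slices[order(idx)]
  structure(list(case_id = case_id, label = label, slices = slices,
                 thickness = thickness),
            class = "case_record")
}

#' Select the representative middle slice of a case
#'
#' Returns the slice at 0-based position `floor((n - 1) / 2)`; for an even
#' slice count this is the lower middle.
#'
#' @param c A `case_record`.
#' @return A single `roi_sample`.
#' @export
select_single <- function(c) {
  n <- length(c$slices)
  if (n == 0) stop_input("empty case")
  c$slices[[floor((n - 1) / 2) + 1]]
}

#' Pool all member slices of training cases in random order
#'
#' Concatenates every member slice of every case, each carrying its case's
#' label, then applies a random permutation drawn from the current RNG
#' state (seed it with [withr::with_seed()] or via the harness).
#'
#' @param cases List of `case_record` objects (training side only).
#' @return List of `roi_sample` objects.
#' @export
expand_all <- function(cases) {
  slices <- unlist(lapply(cases, function(cs) {
    lapply(cs$slices, function(s) { s$label <- cs$label; s })
  }), recursive = FALSE)
  slices[sample.int(length(slices))]
}

#' Majority vote over slice-level hard labels
#'
#' A case is malignant iff strictly more than half of its member slices are
#' called malignant; an exact half (even counts) resolves to benign, per the
#' "more than half" rule.
#'
#' @param case_predictions Character vector of `"benign"`/`"malignant"`.
#' @return `"benign"` or `"malignant"`.
#' @examples
#' vote(c("malignant", "malignant", "benign"))            # malignant
#' vote(c("malignant", "benign", "malignant", "benign"))  # benign (tie)
#' @export
vote <- function(case_predictions) {
  n <- length(case_predictions)
  if (n == 0) stop_input("no slice predictions to vote on")
  bad <- setdiff(unique(case_predictions), c("benign", "malignant"))
  if (length(bad)) stop_input("unknown labels: ", paste(bad, collapse = ", "))
  if (sum(case_predictions == "malignant") > n / 2) "malignant" else "benign"
}
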