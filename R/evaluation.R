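#' Confusion matrices for slide interpretation
#'
#' A small S3 container for label-by-label count matrices as printed in
#' slide-interpretation studies: rows are true classes, columns predicted
#' classes, optionally including an abstain ("indeterminate") column for
#' readers who decline to call a slide.
#'
#' @param counts non-negative integer matrix with row and column names.
#' @param abstain optional name of the abstain column.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, abstain = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry row and column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("labels must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(abstain) && !abstain %in% colnames(counts))
    stop("abstain column '", abstain, "' not present")
  structure(list(counts = counts, abstain = abstain),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = true, cols = predicted")
  if (!is.null(x$abstain)) cat(", abstain = ", x$abstain, sep = "")
  cat(")\n")
  print(x$counts)
  invisible(x)
}

# Columns that participate in accuracy (abstain excluded).
call_columns <- function(cm) {
  cols <- colnames(cm$counts)
  if (!is.null(cm$abstain)) cols <- setdiff(cols, cm$abstain)
  cols
}

#' Overall interpretation accuracy
#'
#' `100 * trace / total` over the non-abstain columns, rounded half-up.
#'
#' @param cm a [confusion_matrix()].
#' @param round_to decimal places (half-up rounding, as printed).
#' @return percentage.
#' @examples
#' cm <- read_confusion(system.file("extdata", "table1.csv",
#'                                  package = "holoGram"))
#' overall_accuracy(cm)   # 92.3
#' @export
overall_accuracy <- function(cm, round_to = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cols <- call_columns(cm)
  m <- cm$counts[, cols, drop = FALSE]
  total <- sum(m)
  if (total == 0) stop("overall_accuracy: undefined for an empty matrix")
  shared <- intersect(rownames(m), cols)
  correct <- sum(vapply(shared, function(l) m[l, l], numeric(1)))
  round_half_up(100 * correct / total, round_to)
}

#' Per-class interpretation accuracy
#'
#' `100 * diagonal / row total` over non-abstain columns for one true
#' class.
#'
#' @param cm a [confusion_matrix()].
#' @param class a row label.
#' @param round_to decimal places.
#' @return percentage.
#' @export
per_class_accuracy <- function(cm, class, round_to = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!class %in% rownames(cm$counts)) stop("unknown class: ", class)
  cols <- call_columns(cm)
  row <- cm$counts[class, cols]
  if (sum(row) == 0) stop("per_class_accuracy: empty row for ", class)
  round_half_up(100 * cm$counts[class, class] / sum(row), round_to)
}

#' Binary Gram-reaction accuracy
#'
#' Collapses the morphology classes into Gram-positive vs Gram-negative
#' groups and reports the per-group accuracy: the fraction of each group's
#' slides called as any class of the same group.
#'
#' @param cm a [confusion_matrix()].
#' @param gram_map named character vector mapping every class to
#'   `"positive"` or `"negative"`.
#' @param round_to decimal places.
#' @return named vector `c(gn, gp)` of percentages.
#' @export
binary_gram_accuracy <- function(cm,
                                 gram_map = c(GNB = "negative",
                                              GPC_clusters = "positive",
                                              GPC_pairs_chains = "positive"),
                                 round_to = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cols <- call_columns(cm)
  unmapped <- setdiff(union(rownames(cm$counts), cols), names(gram_map))
  if (length(unmapped))
    stop("binary_gram_accuracy: unmapped classes: ",
         paste(unmapped, collapse = ", "))
  acc <- function(group) {
    rows <- rownames(cm$counts)[gram_map[rownames(cm$counts)] == group]
    gcols <- cols[gram_map[cols] == group]
    m <- cm$counts[rows, cols, drop = FALSE]
    tot <- sum(m)
    if (tot == 0) stop("binary_gram_accuracy: no slides in group ", group)
    round_half_up(100 * sum(m[, gcols, drop = FALSE]) / tot, round_to)
  }
  c(gn = acc("negative"), gp = acc("positive"))
}

#' Call rate and accuracy among called slides
#'
#' For a matrix with an abstain column: the call rate is the fraction of
#' interpretations other than abstain; the called accuracy is the fraction
#' of correct calls among those.
#'
#' @param cm a [confusion_matrix()] with an abstain column.
#' @param round_to_rate,round_to_acc decimal places for the two results.
#' @return named vector `c(call_rate, called_accuracy)` of percentages.
#' @export
call_rate_and_called_accuracy <- function(cm, round_to_rate = 1,
                                          round_to_acc = 0) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (is.null(cm$abstain))
    stop("call_rate_and_called_accuracy: no abstain column identified")
  total <- sum(cm$counts)
  called <- total - sum(cm$counts[, cm$abstain])
  if (total == 0) stop("empty matrix")
  rate <- round_half_up(100 * called / total, round_to_rate)
  if (called == 0) stop("called accuracy undefined: no calls made")
  cols <- call_columns(cm)
  shared <- intersect(rownames(cm$counts), cols)
  correct <- sum(vapply(shared, function(l) cm$counts[l, l], numeric(1)))
  acc <- round_half_up(100 * correct / called, round_to_acc)
  c(call_rate = rate, called_accuracy = acc)
}

#' Read and write confusion matrices as CSV
#'
#' The CSV has the true-class labels in the first column and predicted
#' classes as the remaining column headers; an `abstain` attribute is
#' inferred from an `Indeterminate` column (case-insensitive) unless
#' given.
#'
#' @param path CSV file path.
#' @param abstain abstain column name, or NA to auto-detect.
#' @return a [confusion_matrix()].
#' @export
read_confusion <- function(path, abstain = NA) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.na(abstain)) {
    hit <- grep("^indeterminate$", colnames(m), ignore.case = TRUE, value = TRUE)
    abstain <- if (length(hit)) hit[1] else NULL
  }
  confusion_matrix(m, abstain = abstain)
}

#' @rdname read_confusion
#' @param cm a [confusion_matrix()] to write.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- data.frame(true = rownames(cm$counts), cm$counts,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate pipeline results into a confusion matrix
#'
#' @param truth,predicted character vectors of true and called categories;
#'   predictions may include `"Undefined"`.
#' @param abstain name used for the abstain column when present in
#'   `predicted`.
#' @return a [confusion_matrix()].
#' @export
tabulate_calls <- function(truth, predicted, abstain = "Undefined") {
  stopifnot(length(truth) == length(predicted))
  rl <- slide_classes()
  cl <- c(slide_classes(), if (abstain %in% predicted) abstain)
  m <- table(factor(truth, levels = rl), factor(predicted, levels = cl))
  m <- matrix(as.integer(m), nrow = length(rl),
              dimnames = list(rl, cl))
  confusion_matrix(m, abstain = if (abstain %in% cl) abstain else NULL)
}
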