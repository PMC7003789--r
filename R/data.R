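#' Contrast-level NMA dataset
#'
#' Builds a validated contrast-level dataset for network meta-analysis. Each
#' row is one two-arm contrast from one study: the observed relative effect
#' `y` of treatment `t2` versus `t1` on an additive scale (e.g. log odds
#' ratio) with standard error `se`. Studies contributing more than one row
#' (multi-arm trials) are accepted; their joint likelihood is handled at
#' fitting time.
#'
#' @param data a data frame with columns `study`, `t1`, `t2`, `y`, `se` (extra
#'   columns are ignored).
#' @param treatments optional character vector fixing the treatment order;
#'   defaults to order of first appearance (t1 before t2, row by row).
#' @param reference reference treatment label; defaults to the first
#'   treatment. All basic parameters are effects versus this treatment.
#' @return an object of class `contrast_data`: a list with elements
#'   `records` (data frame), `treatments` (character) and `reference`.
#' @examples
#' cd <- contrast_data(data.frame(study = "s1", t1 = "A", t2 = "B",
#'                                y = 0.5, se = 0.1))
#' network_summary(cd)
#' @export
contrast_data <- function(data, treatments = NULL, reference = NULL) {
  required <- c("study", "t1", "t2", "y", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_validation("missing required column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  rec <- data.frame(study = as.character(data$study),
                    t1 = as.character(data$t1),
                    t2 = as.character(data$t2),
                    y = as.numeric(data$y),
                    se = as.numeric(data$se),
                    stringsAsFactors = FALSE)
  if (nrow(rec) == 0) stop_validation("dataset has no records")
  bad <- which(!is.finite(rec$y) | !is.finite(rec$se))
  if (length(bad) > 0) {
    stop_validation("non-finite y or se in row(s): ",
                    paste(bad, collapse = ", "))
  }
  bad <- which(rec$se <= 0)
  if (length(bad) > 0) {
    stop_validation("se must be > 0; offending row(s): ",
                    paste(bad, collapse = ", "))
  }
  bad <- which(rec$t1 == rec$t2)
  if (length(bad) > 0) {
    stop_validation("t1 and t2 must differ; offending row(s): ",
                    paste(bad, collapse = ", "))
  }
  seen <- unique(as.vector(rbind(rec$t1, rec$t2)))
  if (is.null(treatments)) {
    treatments <- seen
  } else {
    treatments <- as.character(treatments)
    extra <- setdiff(seen, treatments)
    if (length(extra) > 0) {
      stop_validation("records mention treatment(s) not in `treatments`: ",
                      paste(extra, collapse = ", "))
    }
  }
  if (length(treatments) < 2) stop_validation("need at least 2 treatments")
  reference <- reference %||% treatments[1]
  if (!reference %in% treatments) {
    stop_validation("reference '", reference, "' is not a treatment")
  }
  structure(list(records = rec, treatments = treatments,
                 reference = reference),
            class = "contrast_data")
}

#' Read a contrast-level dataset from a delimited file
#'
#' Reads a CSV (or TSV) file with one row per contrast and a header naming at
#' least `study,t1,t2,y,se`; `columns` can remap nonstandard names.
#'
#' @param path path to the file.
#' @param columns optional named character vector mapping standard names to
#'   the names used in the file, e.g. `c(y = "logOR", se = "stderr")`.
#' @param sep field separator, `","` by default.
#' @inheritParams contrast_data
#' @return a [contrast_data()] object.
#' @export
read_contrast_data <- function(path, columns = NULL, sep = ",",
                               treatments = NULL, reference = NULL) {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (!columns[[std]] %in% names(df)) {
        stop_validation("column '", columns[[std]], "' (mapped to '", std,
                        "') not found in ", path)
      }
      names(df)[names(df) == columns[[std]]] <- std
    }
  }
  contrast_data(df, treatments = treatments, reference = reference)
}

#' Treatment class map
#'
#' Assigns each non-control treatment to exactly one class of similar
#' treatments, for use with the multi-class shrinkage models (IV and V).
#'
#' @param classes named character vector: names are treatment labels, values
#'   class labels; or a data frame with columns `treatment` and `class`.
#' @param control optional treatment label excluded from all classes (the
#'   network's control arm for Model IV; Model V has none).
#' @return an object of class `class_map`.
#' @examples
#' class_map(c(B = "c1", C = "c1", D = "c2"), control = "A")
#' @export
class_map <- function(classes, control = NULL) {
  if (is.data.frame(classes)) {
    if (!all(c("treatment", "class") %in% names(classes))) {
      stop_validation("class data frame needs columns `treatment`, `class`")
    }
    classes <- setNames(as.character(classes$class),
                        as.character(classes$treatment))
  }
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stop_validation("`classes` must be a named vector (treatment -> class)")
  }
  if (anyDuplicated(names(classes))) {
    stop_validation("each treatment may appear in only one class")
  }
  if (!is.null(control) && control %in% names(classes)) {
    stop_validation("control treatment '", control,
                    "' must not belong to a class")
  }
  structure(list(classes = classes, control = control), class = "class_map")
}

#' Read a class map from a CSV file
#'
#' Expects columns `treatment,class`; a row whose class is `control` marks
#' the control treatment.
#'
#' @param path path to the CSV file.
#' @return a [class_map()] object.
#' @export
read_class_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("treatment", "class") %in% names(df))) {
    stop_validation("class file needs columns `treatment`, `class`")
  }
  is_control <- tolower(df$class) == "control"
  control <- if (any(is_control)) df$treatment[is_control][1] else NULL
  class_map(df[!is_control, , drop = FALSE], control = control)
}

#' Summarise network structure
#'
#' @param data a [contrast_data()] object.
#' @return a list of class `network_summary` with elements `n_treatments`,
#'   `n_studies`, `n_records`, `comparisons` (per-pair study counts),
#'   `connected` (all treatments reachable from the reference through
#'   observed comparisons) and `geometry` (`"star"` if every record involves
#'   the reference, `"complete"` if all pairs are observed, else `"other"`).
#' @examples
#' cd <- contrast_data(data.frame(study = c("s1", "s2"), t1 = c("A", "A"),
#'                                t2 = c("B", "C"), y = 0, se = 1))
#' network_summary(cd)
#' @export
network_summary <- function(data) {
  stopifnot(inherits(data, "contrast_data"))
  rec <- data$records
  trt <- data$treatments
  pair_key <- function(a, b) {
    i <- match(a, trt); j <- match(b, trt)
    paste(trt[pmin(i, j)], trt[pmax(i, j)], sep = " vs ")
  }
  comparisons <- table(pair_key(rec$t1, rec$t2))
  touches_ref <- rec$t1 == data$reference | rec$t2 == data$reference
  n_pairs <- length(trt) * (length(trt) - 1) / 2
  geometry <- if (all(touches_ref)) "star"
              else if (length(comparisons) == n_pairs) "complete"
              else "other"
  structure(list(
    n_treatments = length(trt),
    n_studies = length(unique(rec$study)),
    n_records = nrow(rec),
    reference = data$reference,
    comparisons = comparisons,
    connected = is_connected(data),
    geometry = geometry
  ), class = "network_summary")
}

# breadth-first reachability from the reference over observed comparisons
is_connected <- function(data) {
  trt <- data$treatments
  adj <- lapply(setNames(vector("list", length(trt)), trt), function(x) character())
  for (i in seq_len(nrow(data$records))) {
    a <- data$records$t1[i]; b <- data$records$t2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- data$reference
  frontier <- data$reference
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(trt)
}

#' Design matrix of basic parameters
#'
#' Each record's mean is `d[t2] - d[t1]` with the reference effect fixed at
#' zero, so a row carries +1 in the column of `t2` and -1 in the column of
#' `t1` (reference columns dropped). With `symmetric = TRUE` all `T` columns
#' are kept (no treatment is privileged), as used by the symmetric models.
#'
#' @param data a [contrast_data()] object.
#' @param symmetric keep a column for every treatment instead of dropping the
#'   reference.
#' @return numeric matrix with one row per record, columns named by
#'   treatment.
#' @export
design_matrix <- function(data, symmetric = FALSE) {
  stopifnot(inherits(data, "contrast_data"))
  trt <- data$treatments
  rec <- data$records
  X <- matrix(0, nrow(rec), length(trt), dimnames = list(NULL, trt))
  X[cbind(seq_len(nrow(rec)), match(rec$t2, trt))] <- 1
  X[cbind(seq_len(nrow(rec)), match(rec$t1, trt))] <- -1
  if (!symmetric) X <- X[, setdiff(trt, data$reference), drop = FALSE]
  X
}

#' @export
print.contrast_data <- function(x, ...) {
  cat("Contrast-level NMA dataset\n")
  cat("  treatments:", length(x$treatments),
      paste0("(reference: ", x$reference, ")\n"))
  cat("  studies:", length(unique(x$records$study)),
      "  records:", nrow(x$records), "\n")
  print(head(x$records, 6))
  if (nrow(x$records) > 6) cat("  ...", nrow(x$records) - 6, "more rows\n")
  invisible(x)
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network: ", x$n_treatments, " treatments, ", x$n_studies,
      " studies (", x$n_records, " contrasts)\n", sep = "")
  cat("  geometry:", x$geometry,
      "| connected:", x$connected,
      "| reference:", x$reference, "\n")
  print(x$comparisons)
  invisible(x)
}
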