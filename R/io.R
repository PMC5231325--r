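#' Read and write datasets as CSV
#'
#' Univariate datasets are stored as a single-column CSV with header `y`;
#' longitudinal datasets in long format with columns
#' `subject_id,time,y[,covariate...]`. The generating labels, when present,
#' go to a separate "truth" sidecar file (`label` column, plus
#' `subject_id` for longitudinal data) so that fitting code can be pointed
#' at the data file alone.
#'
#' @param data A `"univariate_dataset"` or `"longitudinal_dataset"`.
#' @param path Path of the data CSV.
#' @param truth_path Optional path for the labels sidecar CSV.
#' @return `write_dataset_csv` invisibly returns `path`;
#'   `read_univariate_csv` / `read_longitudinal_csv` return the dataset
#'   object (with `true_labels` filled from `truth_path` when given,
#'   otherwise `NA`).
#' @export
write_dataset_csv <- function(data, path, truth_path = NULL) {
  if (inherits(data, "univariate_dataset")) {
    write.csv(data.frame(y = data$values), path, row.names = FALSE)
    if (!is.null(truth_path))
      write.csv(data.frame(label = data$true_labels), truth_path,
                row.names = FALSE)
  } else if (inherits(data, "longitudinal_dataset")) {
    write.csv(data$data, path, row.names = FALSE)
    if (!is.null(truth_path))
      write.csv(data.frame(subject_id = seq_along(data$true_labels),
                           label = data$true_labels),
                truth_path, row.names = FALSE)
  } else stop("unsupported dataset class")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_univariate_csv <- function(path, truth_path = NULL) {
  df <- read.csv(path)
  if (!("y" %in% names(df))) stop("expected a column named 'y' in ", path)
  labels <- if (!is.null(truth_path)) as.integer(read.csv(truth_path)$label)
    else rep(NA_integer_, nrow(df))
  structure(list(values = as.numeric(df$y), true_labels = labels),
            class = "univariate_dataset")
}

#' @rdname write_dataset_csv
#' @export
read_longitudinal_csv <- function(path, truth_path = NULL) {
  df <- read.csv(path)
  need <- c("subject_id", "time", "y")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  n_subj <- length(unique(df$subject_id))
  labels <- if (!is.null(truth_path)) {
    tr <- read.csv(truth_path)
    as.integer(tr$label[order(tr$subject_id)])
  } else rep(NA_integer_, n_subj)
  structure(list(data = df, true_labels = labels),
            class = "longitudinal_dataset")
}
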