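#' Multi-subject intervention time-series collection
#'
#' The universal input object of the package: for each subject, a
#' taxon-by-time abundance matrix and an intervention-by-time matrix sharing
#' one strictly increasing time grid, plus an optional static covariate vector
#' per subject. Taxon, intervention and covariate sets are identical across
#' subjects.
#'
#' @param abundances named list (one element per subject) of J x T numeric
#'   matrices, taxa in rows. Row names are taxon identifiers.
#' @param interventions named list of D x T numeric matrices (typically in
#'   \[0, 1\]), aligned with `abundances` times. Row names identify the
#'   intervention channels.
#' @param times named list of strictly increasing numeric time vectors, one
#'   per subject.
#' @param covariates optional n x S numeric matrix of static subject
#'   covariates (rows = subjects); `NULL` means S = 0.
#' @return an object of class `study_collection`.
#' @export
study_collection <- function(abundances, interventions, times, covariates = NULL) {
  subjects <- names(abundances)
  if (is.null(subjects) || any(subjects == ""))
    stop("abundances must be a named list keyed by subject id")
  if (!identical(names(interventions), subjects) || !identical(names(times), subjects))
    stop("abundances, interventions and times must share subject names in order")
  taxa <- rownames(abundances[[1L]])
  if (is.null(taxa)) taxa <- paste0("tax", seq_len(nrow(abundances[[1L]])))
  ints <- rownames(interventions[[1L]])
  if (is.null(ints)) ints <- paste0("w", seq_len(nrow(interventions[[1L]])))
  for (s in subjects) {
    tm <- times[[s]]
    if (any(diff(tm) <= 0)) stop("non-increasing time grid for subject ", s)
    if (ncol(abundances[[s]]) != length(tm) || ncol(interventions[[s]]) != length(tm))
      stop("abundances/interventions of subject ", s, " not aligned with its time grid")
    if (nrow(abundances[[s]]) != length(taxa))
      stop("taxon dimension differs for subject ", s)
    if (nrow(interventions[[s]]) != length(ints))
      stop("intervention dimension differs for subject ", s)
    if (anyNA(abundances[[s]]) || anyNA(interventions[[s]]))
      stop("missing values in series of subject ", s)
    rownames(abundances[[s]]) <- taxa
    rownames(interventions[[s]]) <- ints
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(subjects))
      stop("covariates must have one row per subject")
    rownames(covariates) <- subjects
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
  }
  structure(
    list(abundances = abundances, interventions = interventions,
         times = times, covariates = covariates,
         subjects = subjects, taxa = taxa, intervention_names = ints,
         covariate_names = if (is.null(covariates)) character(0) else colnames(covariates),
         normalization = NULL),
    class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat("study_collection:", length(x$subjects), "subjects,",
      length(x$taxa), "taxa,", length(x$intervention_names), "intervention(s),",
      length(x$covariate_names), "covariate(s)\n")
  tp <- vapply(x$times, length, 1L)
  cat("  timepoints per subject:", paste(range(tp), collapse = "-"), "\n")
  if (!is.null(x$normalization))
    cat("  normalization:", x$normalization$method, "\n")
  invisible(x)
}

n_subjects <- function(x) length(x$subjects)
n_taxa <- function(x) length(x$taxa)

#' Read a study collection from delimited files
#'
#' Expects the standard long/wide layout: a counts table (taxa in rows, first
#' column the taxon id, one column per sample), a samples table with columns
#' `sample_id`, `subject_id`, `time`, an interventions table with columns
#' `subject_id`, `time`, `intervention`, `value`, and an optional covariates
#' table with `subject_id` plus one column per covariate. Intervention values
#' default to 0 at subject times absent from the interventions table.
#'
#' @param counts_file,samples_file,interventions_file,covariates_file paths;
#'   TSV or CSV (inferred from the extension). `covariates_file = NULL` means
#'   no static covariates.
#' @return a [study_collection].
#' @export
read_study <- function(counts_file, samples_file, interventions_file,
                       covariates_file = NULL) {
  rd <- function(f) {
    sep <- if (grepl("\\.csv$", f)) "," else "\t"
    read.table(f, header = TRUE, sep = sep, comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  counts <- rd(counts_file)
  taxa <- as.character(counts[[1L]])
  cmat <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(cmat) <- taxa
  samples <- rd(samples_file)
  need <- c("sample_id", "subject_id", "time")
  if (!all(need %in% names(samples)))
    stop("samples file must have columns: ", paste(need, collapse = ", "))
  iv <- rd(interventions_file)
  ints <- sort(unique(as.character(iv$intervention)))
  subjects <- unique(as.character(samples$subject_id))
  abundances <- list(); interventions <- list(); times <- list()
  for (s in subjects) {
    sm <- samples[samples$subject_id == s, , drop = FALSE]
    sm <- sm[order(sm$time), , drop = FALSE]
    times[[s]] <- as.numeric(sm$time)
    abundances[[s]] <- cmat[, as.character(sm$sample_id), drop = FALSE]
    W <- matrix(0, length(ints), nrow(sm), dimnames = list(ints, NULL))
    ivs <- iv[iv$subject_id == s, , drop = FALSE]
    for (k in seq_len(nrow(ivs))) {
      j <- match(ivs$time[k], times[[s]])
      if (!is.na(j)) W[as.character(ivs$intervention[k]), j] <- ivs$value[k]
    }
    interventions[[s]] <- W
  }
  covariates <- NULL
  if (!is.null(covariates_file)) {
    cv <- rd(covariates_file)
    covariates <- as.matrix(cv[match(subjects, as.character(cv$subject_id)),
                               -match("subject_id", names(cv)), drop = FALSE])
    rownames(covariates) <- subjects
  }
  study_collection(abundances, interventions, times, covariates)
}

#' Write a study collection to a directory of TSV files
#'
#' Emits `counts.tsv`, `samples.tsv`, `interventions.tsv` and, when covariates
#' are present, `covariates.tsv`, in the layout accepted by [read_study()].
#'
#' @param collection a [study_collection].
#' @param dir output directory (created if needed).
#' @param comment optional header comment line written atop each file.
#' @return `dir`, invisibly.
#' @export
write_study <- function(collection, dir, comment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    path <- file.path(dir, f)
    con <- file(path, "w")
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  sample_ids <- unlist(lapply(collection$subjects, function(s)
    paste0(s, "_t", seq_along(collection$times[[s]]))))
  counts <- do.call(cbind, collection$abundances)
  colnames(counts) <- sample_ids
  wr(data.frame(taxon = collection$taxa, counts, check.names = FALSE), "counts.tsv")
  samples <- do.call(rbind, lapply(collection$subjects, function(s)
    data.frame(sample_id = paste0(s, "_t", seq_along(collection$times[[s]])),
               subject_id = s, time = collection$times[[s]])))
  wr(samples, "samples.tsv")
  iv <- do.call(rbind, lapply(collection$subjects, function(s) {
    W <- collection$interventions[[s]]
    do.call(rbind, lapply(rownames(W), function(w)
      data.frame(subject_id = s, time = collection$times[[s]],
                 intervention = w, value = as.numeric(W[w, ]))))
  }))
  wr(iv, "interventions.tsv")
  if (!is.null(collection$covariates))
    wr(data.frame(subject_id = collection$subjects, collection$covariates,
                  check.names = FALSE), "covariates.tsv")
  invisible(dir)
}

#' Interpolate every subject onto a regular time grid
#'
#' Resamples each subject's abundance and intervention series onto an
#' arithmetic grid with spacing `step` spanning that subject's observed
#' \[first, last\] times, using natural cubic splines per taxon/channel.
#' Cubic splines reproduce the observations at the knots, so series already on
#' the target grid are returned unchanged. Interpolated abundances are clipped
#' at 0; intervention channels whose raw values lie in \[0, 1\] are clipped to
#' \[0, 1\] (fractional values in transition windows are expected and kept).
#'
#' @param collection a [study_collection].
#' @param step positive grid spacing in the study's time units.
#' @return an interpolated [study_collection] on regular grids.
#' @export
interpolate_to_grid <- function(collection, step) {
  stopifnot(step > 0)
  interp_mat <- function(M, tm, grid, clip01 = FALSE, clip0 = FALSE) {
    out <- matrix(0, nrow(M), length(grid), dimnames = list(rownames(M), NULL))
    for (r in seq_len(nrow(M))) {
      f <- splinefun(tm, M[r, ], method = "natural")
      v <- f(grid)
      if (clip0) v <- pmax(v, 0)
      if (clip01 && all(M[r, ] >= 0) && all(M[r, ] <= 1)) v <- pmin(pmax(v, 0), 1)
      out[r, ] <- v
    }
    out
  }
  ab <- list(); iv <- list(); tms <- list()
  for (s in collection$subjects) {
    tm <- collection$times[[s]]
    if (length(tm) < 4L)
      stop("subject ", s, " has fewer than 4 timepoints; cubic spline interpolation needs at least 4")
    grid <- seq(tm[1L], tm[length(tm)], by = step)
    ab[[s]] <- interp_mat(collection$abundances[[s]], tm, grid, clip0 = TRUE)
    iv[[s]] <- interp_mat(collection$interventions[[s]], tm, grid, clip01 = TRUE)
    tms[[s]] <- grid
  }
  out <- study_collection(ab, iv, tms, collection$covariates)
  out$normalization <- collection$normalization
  out
}

#' Filter taxa by prevalence
#'
#' Keeps taxa present (abundance strictly greater than 0) in at least
#' `min_fraction` of all samples, pooled over subjects and timepoints. Taxon
#' order is preserved.
#'
#' @param collection a [study_collection].
#' @param min_fraction required presence fraction in \[0, 1\].
#' @return the filtered [study_collection].
#' @export
filter_prevalence <- function(collection, min_fraction) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  pooled <- do.call(cbind, collection$abundances)
  prev <- rowMeans(pooled > 0)
  keep <- prev >= min_fraction
  if (!any(keep))
    stop("prevalence filter removed every taxon; lower min_fraction (max observed prevalence: ",
         signif(max(prev), 3), ")")
  out <- collection
  out$abundances <- lapply(collection$abundances, function(M) M[keep, , drop = FALSE])
  out$taxa <- collection$taxa[keep]
  out
}

#' Restrict a collection to a subset of subjects
#'
#' @param collection a [study_collection].
#' @param subjects character vector of subject ids to keep.
#' @return the restricted [study_collection].
#' @export
subset_subjects <- function(collection, subjects) {
  stopifnot(all(subjects %in% collection$subjects))
  out <- collection
  out$subjects <- subjects
  out$abundances <- collection$abundances[subjects]
  out$interventions <- collection$interventions[subjects]
  out$times <- collection$times[subjects]
  if (!is.null(collection$covariates))
    out$covariates <- collection$covariates[subjects, , drop = FALSE]
  out
}
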