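## Reading and writing per-patient tables (Kaggle-sepsis-style CSV/PSV) and
## feature-graph serialization.

dialectSep <- function(dialect) {
  switch(match.arg(dialect, c("csv", "psv")), csv = ",", psv = "|")
}

dialectExt <- function(dialect) match.arg(dialect, c("csv", "psv"))

## full-precision numeric formatting so write -> read round-trips doubles
fmtNum <- function(x, naString) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- naString
  out
}

#' Write a cohort as per-patient tables
#'
#' One file per patient in \code{dir}, named \code{<patientId>.<dialect>},
#' with columns \code{Hour}, the 12 physiological features, and
#' \code{AKI_Label} (0 before onset, 1 from onset on, Kaggle-sepsis style).
#' Missing cells are written as \code{"NaN"} in the pipe-separated dialect and
#' as empty cells in CSV; values are written at full double precision so that
#' write-then-read reproduces records exactly.
#'
#' @param cohort An \code{AkiCohort}.
#' @param dir Output directory (created if absent).
#' @param dialect \code{"psv"} (pipe-separated, Kaggle layout) or
#'   \code{"csv"}.
#' @return Invisibly, the vector of file paths written.
#' @export
writeCohort <- function(cohort, dir, dialect = c("psv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- dialectSep(dialect)
  naString <- if (dialect == "psv") "NaN" else ""
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort@records, function(r) {
    L <- nrow(r@series)
    lab <- integer(L)
    if (r@label == 1L) lab[seq_len(L) >= r@akiOnsetHour] <- 1L
    cols <- c(
      list(Hour = as.character(seq_len(L))),
      lapply(akiFeatures(), function(f) fmtNum(r@series[, f], naString)),
      list(AKI_Label = as.character(lab))
    )
    names(cols) <- c("Hour", akiFeatures(), "AKI_Label")
    path <- file.path(dir, paste0(r@patientId, ".", dialect))
    lines <- c(
      paste(names(cols), collapse = sep),
      do.call(paste, c(unname(cols), list(sep = sep)))
    )
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a cohort from per-patient tables
#'
#' Reads every \code{*.csv} or \code{*.psv} file in \code{dir}. The 12
#' required physiological columns are resolved through \code{nameMap}
#' (canonical name -> file column name); a file lacking any required column
#' -- in particular creatinine -- is a hard error. Non-numeric cells are
#' reported with their row and column. Missing cells may be empty,
#' \code{"NA"} or \code{"NaN"}. An \code{AKI_Label} column, when present,
#' recovers the label and onset hour; otherwise records are read unlabeled
#' (label 0) and can be relabeled with \code{\link{labelCohort}}.
#'
#' @param dir Directory of per-patient files.
#' @param dialect \code{"psv"} or \code{"csv"}.
#' @param nameMap Named character vector mapping canonical feature names to
#'   file column names (default: identity).
#' @return An \code{\link{akiCohort}}.
#' @export
readCohort <- function(dir, dialect = c("psv", "csv"),
                       nameMap = stats::setNames(akiFeatures(), akiFeatures())) {
  dialect <- match.arg(dialect)
  sep <- dialectSep(dialect)
  files <- sort(list.files(dir, pattern = paste0("\\.", dialect, "$"),
                           full.names = TRUE))
  if (length(files) == 0L) stop("no .", dialect, " files found in ", dir)
  records <- lapply(files, function(path) {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            na.strings = character(0))
    need <- unname(nameMap[akiFeatures()])
    missingCols <- need[!need %in% names(df)]
    if (length(missingCols)) {
      stop(sprintf(
        "%s: required column(s) missing: %s", basename(path),
        paste(missingCols, collapse = ", ")
      ))
    }
    parseCol <- function(colName) {
      raw <- df[[colName]]
      blank <- raw %in% c("", "NA", "NaN")
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!blank & is.na(val))
      if (length(bad)) {
        stop(sprintf(
          "%s: non-numeric value '%s' at row %d, column %s",
          basename(path), raw[bad[1L]], bad[1L], colName
        ))
      }
      val[blank] <- NA_real_
      val
    }
    series <- vapply(need, parseCol, numeric(nrow(df)))
    if (nrow(df) == 1L) series <- matrix(series, nrow = 1L)
    colnames(series) <- akiFeatures()
    pid <- sub(paste0("\\.", dialect, "$"), "", basename(path))
    label <- 0L
    onset <- NA_integer_
    if ("AKI_Label" %in% names(df)) {
      labCol <- parseCol("AKI_Label")
      if (any(labCol == 1, na.rm = TRUE)) {
        label <- 1L
        onset <- as.integer(which(labCol == 1)[1L])
      }
    }
    patientRecord(pid, series, akiOnsetHour = onset, label = label)
  })
  akiCohort(records)
}

#' Serialize feature graphs as CSV tables
#'
#' Writes a list of \code{FeatureGraph} objects as three CSV files in
#' \code{dir}: \code{graphs.csv} (patient id, label, end hour, T, steps),
#' \code{edges.csv} (patient id, i, j, weight; upper triangle only) and
#' \code{features.csv} (patient id, node, t, one column per history step).
#' The round trip through \code{readFeatureGraphs} is loss-free.
#'
#' @param graphs List of \code{FeatureGraph}.
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeFeatureGraphs <- function(graphs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- do.call(rbind, lapply(graphs, function(g) {
    d <- dim(g@nodeFeatures)
    data.frame(patient_id = g@patientId, label = g@label,
               end_hour = g@endHour, T = d[2], steps = d[3],
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(graphs, function(g) {
    idx <- which(upper.tri(g@adjacency) & g@adjacency != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(patient_id = g@patientId, i = idx[, 1], j = idx[, 2],
               weight = sprintf("%.17g", g@adjacency[idx]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(patient_id = character(0), i = integer(0),
                        j = integer(0), weight = character(0))
  }
  feats <- do.call(rbind, lapply(graphs, function(g) {
    d <- dim(g@nodeFeatures)
    grid <- expand.grid(node = seq_len(d[1]), t = seq_len(d[2]))
    vals <- vapply(seq_len(d[3]), function(s) {
      sprintf("%.17g", g@nodeFeatures[cbind(grid$node, grid$t, s)])
    }, character(nrow(grid)))
    vals <- matrix(vals, nrow = nrow(grid))
    colnames(vals) <- paste0("step", seq_len(d[3]))
    cbind(data.frame(patient_id = g@patientId, node = grid$node, t = grid$t,
                     stringsAsFactors = FALSE), as.data.frame(vals))
  }))
  utils::write.table(meta, file.path(dir, "graphs.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(edges, file.path(dir, "edges.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(feats, file.path(dir, "features.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeFeatureGraphs
#' @export
readFeatureGraphs <- function(dir) {
  meta <- utils::read.table(file.path(dir, "graphs.csv"), header = TRUE,
                            sep = ",", stringsAsFactors = FALSE)
  edges <- utils::read.table(file.path(dir, "edges.csv"), header = TRUE,
                             sep = ",", stringsAsFactors = FALSE)
  feats <- utils::read.table(file.path(dir, "features.csv"), header = TRUE,
                             sep = ",", stringsAsFactors = FALSE)
  N <- 12L
  lapply(seq_len(nrow(meta)), function(k) {
    m <- meta[k, ]
    A <- matrix(0, N, N)
    e <- edges[edges$patient_id == m$patient_id, , drop = FALSE]
    if (nrow(e)) {
      A[cbind(e$i, e$j)] <- e$weight
      A[cbind(e$j, e$i)] <- e$weight
    }
    f <- feats[feats$patient_id == m$patient_id, , drop = FALSE]
    arr <- array(0, dim = c(N, m$T, m$steps))
    for (s in seq_len(m$steps)) {
      arr[cbind(f$node, f$t, s)] <- f[[paste0("step", s)]]
    }
    dimnames(A) <- list(akiFeatures(), akiFeatures())
    new("FeatureGraph",
      nodeIds = akiFeatures(), adjacency = A, nodeFeatures = arr,
      label = as.integer(m$label), patientId = as.character(m$patient_id),
      endHour = as.integer(m$end_hour)
    )
  })
}
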