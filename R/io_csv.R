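#' Write a trial to the CSV dialect
#'
#' Two files. `markers.csv`: header `time,<label>_X,<label>_Y,<label>_Z,...`,
#' one row per frame, occluded samples empty. `forces.csv`: header
#' `time,plate1_Fx,plate1_Fy,plate1_Fz,plate2_Fx,plate2_Fy,plate2_Fz`.
#' Rates are recoverable from the time column and are also written as a
#' `# rate: <Hz>` comment line above each header.
#'
#' @param trial a [trial()].
#' @param marker_path,force_path output paths.
#' @return invisibly, the two paths.
#' @export
write_trial_csv <- function(trial, marker_path, force_path) {
  mk <- trial$markers
  n <- nrow(mk[[1]]$positions)
  rate <- mk[[1]]$rate
  cols <- list(time = sprintf("%.10g", (seq_len(n) - 1) / rate))
  for (m in mk) {
    pos <- m$positions
    pos[m$occluded, ] <- NA
    for (j in 1:3) {
      v <- sprintf("%.9f", pos[, j])
      v[is.na(pos[, j])] <- ""
      cols[[paste0(m$label, "_", c("X", "Y", "Z")[j])]] <- v
    }
  }
  con <- file(marker_path, "w")
  writeLines(sprintf("# rate: %g", rate), con)
  utils::write.csv(as.data.frame(cols, check.names = FALSE), con,
                   row.names = FALSE, quote = FALSE)
  close(con)

  frate <- trial$plates[[1]]$rate
  nf <- length(trial$plates[[1]]$fz)
  fd <- data.frame(time = sprintf("%.10g", (seq_len(nf) - 1) / frate))
  for (p in trial$plates) {
    fd[[sprintf("plate%d_Fx", p$plate_id)]] <- sprintf("%.6f", p$fx)
    fd[[sprintf("plate%d_Fy", p$plate_id)]] <- sprintf("%.6f", p$fy)
    fd[[sprintf("plate%d_Fz", p$plate_id)]] <- sprintf("%.6f", p$fz)
  }
  con <- file(force_path, "w")
  writeLines(sprintf("# rate: %g", frate), con)
  utils::write.csv(fd, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(marker_path, force_path))
}

read_rate_header <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# rate:", first)) return(NULL)
  as.numeric(sub("^# rate:\\s*", "", first))
}

read_csv_numeric <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character")
  for (nm in names(df)) {
    v <- df[[nm]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric value '", v[bad[1]], "' in column '", nm,
           "' at data row ", bad[1], " of ", path, call. = FALSE)
    }
    df[[nm]] <- num
  }
  df
}

#' Read a trial from the CSV dialect
#'
#' @param marker_path,force_path paths written by [write_trial_csv()] (or any
#'   files following the documented dialect).
#' @param alias_map optional named character vector mapping file labels to
#'   canonical labels, e.g. `c(R_ACROMION = "shoulder_peak_right")`.
#' @param meta metadata list merged into the trial.
#' @return a [trial()].
#' @export
read_trial_csv <- function(marker_path, force_path, alias_map = NULL,
                           meta = list()) {
  md <- read_csv_numeric(marker_path)
  mrate <- read_rate_header(marker_path)
  if (is.null(mrate)) {
    mrate <- 1 / stats::median(diff(md$time))
  }
  cn <- setdiff(names(md), "time")
  labels <- unique(sub("_[XYZ]$", "", cn))
  incomplete <- unlist(lapply(labels, function(lab) {
    setdiff(paste0(lab, "_", c("X", "Y", "Z")), cn)
  }))
  if (length(incomplete) > 0) {
    stop("marker columns not in X/Y/Z triplets; missing: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  markers <- list()
  for (lab in labels) {
    need <- paste0(lab, "_", c("X", "Y", "Z"))
    miss <- setdiff(need, cn)
    if (length(miss) > 0) {
      stop("marker '", lab, "' missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    pos <- as.matrix(md[need])
    occ <- apply(is.na(pos), 1, any)
    pos[occ, ] <- 0
    canon <- if (!is.null(alias_map) && lab %in% names(alias_map)) {
      unname(alias_map[[lab]])
    } else lab
    markers[[canon]] <- marker_trajectory(canon, pos, mrate, occ)
  }

  fdf <- read_csv_numeric(force_path)
  frate <- read_rate_header(force_path)
  if (is.null(frate)) frate <- 1 / stats::median(diff(fdf$time))
  plates <- lapply(1:2, function(i) {
    need <- sprintf("plate%d_F%s", i, c("x", "y", "z"))
    miss <- setdiff(need, names(fdf))
    if (length(miss) > 0) {
      stop("force file missing column(s): ", paste(miss, collapse = ", "),
           "; available: ", paste(names(fdf), collapse = ", "),
           call. = FALSE)
    }
    force_channel(i, fdf[[need[1]]], fdf[[need[2]]], fdf[[need[3]]], frate)
  })
  align_clocks(trial(markers, plates, meta))
}
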