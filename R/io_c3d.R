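# Minimal self-contained C3D support (little-endian / "Intel" processor
# type, floating-point point and analog data). Covers the subset this
# package writes: one point group, one analog group holding the two plates'
# force channels, labels, rates, units. Enough for interchange with standard
# tools; not a general-purpose C3D library.

BLOCK <- 512L

w_i8 <- function(con, x) writeBin(as.integer(x), con, size = 1)
w_i16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
w_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4, endian = "little")
w_chr <- function(con, s) writeBin(charToRaw(s), con)

# one parameter record (type: -1 char, 2 int16, 4 float)
w_param <- function(con, name, group_id, type, dims, data) {
  w_i8(con, nchar(name)); w_i8(con, group_id); w_chr(con, name)
  sizes <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)
  dsize <- sizes[[as.character(type)]] * max(1L, prod(dims))
  # offset: from start of the offset field to the next record's first byte
  offset <- 2L + 1L + 1L + length(dims) + dsize + 1L
  w_i16(con, offset)
  w_i8(con, type); w_i8(con, length(dims))
  if (length(dims) > 0) w_i8(con, dims)
  if (type == -1) {
    w_chr(con, paste(data, collapse = ""))
  } else if (type == 2) {
    w_i16(con, data)
  } else {
    w_f32(con, data)
  }
  w_i8(con, 0)  # no description
}

w_group <- function(con, name, group_id) {
  w_i8(con, nchar(name)); w_i8(con, -group_id); w_chr(con, name)
  w_i16(con, 2L + 1L)  # offset field + desc length byte
  w_i8(con, 0)
}

pad_labels <- function(labels) {
  w <- max(nchar(labels))
  vapply(labels, function(s) formatC(s, width = w, flag = "-"), character(1))
}

#' Write a trial as a C3D file
#'
#' Point data are stored in metres (`POINT:UNITS = "m"`), forces in newtons,
#' both as 32-bit floats (`POINT:SCALE = -1`). Occluded frames get residual
#' -1. The analog rate must be an integer multiple of the point rate.
#'
#' @param trial a [trial()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trial_c3d <- function(trial, path) {
  mk <- trial$markers
  npts <- length(mk)
  nframes <- nrow(mk[[1]]$positions)
  if (nframes > 32767) stop("C3D writer limited to 32767 frames", call. = FALSE)
  prate <- mk[[1]]$rate
  arate <- trial$plates[[1]]$rate
  spf <- arate / prate
  if (spf != round(spf)) {
    stop("analog rate must be an integer multiple of point rate", call. = FALSE)
  }
  spf <- as.integer(spf)
  achan <- 6L  # plate{1,2} x {Fx,Fy,Fz}
  alabels <- c(t(outer(c("plate1_F", "plate2_F"), c("x", "y", "z"), paste0)))
  plabels <- pad_labels(names(mk))
  alab_p <- pad_labels(alabels)

  # parameter section layout, then sizes
  tmp <- rawConnection(raw(0), "wb")
  w_i8(tmp, c(1L, 80L, 0L, 84L))  # 84 = Intel processor type
  w_group(tmp, "POINT", 1L)
  w_param(tmp, "USED", 1L, 2, integer(0), npts)
  w_param(tmp, "FRAMES", 1L, 2, integer(0), nframes)
  w_param(tmp, "SCALE", 1L, 4, integer(0), -1)
  w_param(tmp, "RATE", 1L, 4, integer(0), prate)
  w_param(tmp, "DATA_START", 1L, 2, integer(0), 0L)  # patched below
  w_param(tmp, "UNITS", 1L, -1, 1L, "m")
  w_param(tmp, "LABELS", 1L, -1, c(nchar(plabels[1]), npts), plabels)
  w_group(tmp, "ANALOG", 2L)
  w_param(tmp, "USED", 2L, 2, integer(0), achan)
  w_param(tmp, "RATE", 2L, 4, integer(0), arate)
  w_param(tmp, "GEN_SCALE", 2L, 4, integer(0), 1)
  w_param(tmp, "SCALE", 2L, 4, achan, rep(1, achan))
  w_param(tmp, "OFFSET", 2L, 2, achan, rep(0L, achan))
  w_param(tmp, "UNITS", 2L, -1, c(1L, achan), rep("N", achan))
  w_param(tmp, "LABELS", 2L, -1, c(nchar(alab_p[1]), achan), alab_p)
  w_i8(tmp, 0)  # terminator record
  pbytes <- rawConnectionValue(tmp); close(tmp)
  nparam_blocks <- as.integer(ceiling(length(pbytes) / BLOCK))
  data_start <- 2L + nparam_blocks
  pbytes[3] <- as.raw(nparam_blocks)

  # patch POINT:DATA_START value (locate the record by name bytes)
  pat <- charToRaw("DATA_START")
  hit <- which(vapply(seq_len(length(pbytes) - length(pat)), function(i) {
    all(pbytes[i:(i + length(pat) - 1)] == pat)
  }, logical(1)))[1]
  off <- hit + length(pat) + 2L + 2L  # offset field, type, ndims
  pbytes[off:(off + 1)] <- writeBin(as.integer(data_start), raw(), size = 2,
                                    endian = "little")

  con <- file(path, "wb")
  on.exit(close(con))
  # --- header block
  w_i8(con, c(2L, 80L))
  w_i16(con, c(npts, achan * spf, 1L, nframes, 10L))
  w_f32(con, -1)          # 3D scale: negative => float data
  w_i16(con, data_start)
  w_i16(con, spf)
  w_f32(con, prate)
  pad <- BLOCK - 2L - 2L * 5L - 4L - 2L - 2L - 4L
  writeBin(raw(pad), con)
  # --- parameter blocks
  writeBin(pbytes, con)
  writeBin(raw(nparam_blocks * BLOCK - length(pbytes)), con)
  # --- data: per frame, points (x,y,z,residual) then spf analog sub-frames
  pos <- array(0, c(nframes, 4L, npts))
  for (i in seq_len(npts)) {
    pos[, 1:3, i] <- mk[[i]]$positions
    pos[, 4, i] <- ifelse(mk[[i]]$occluded, -1, 0)
  }
  an <- matrix(0, nframes * spf, achan)
  for (p in 1:2) {
    an[, (p - 1) * 3 + 1] <- trial$plates[[p]]$fx
    an[, (p - 1) * 3 + 2] <- trial$plates[[p]]$fy
    an[, (p - 1) * 3 + 3] <- trial$plates[[p]]$fz
  }
  out <- numeric(nframes * (4L * npts + spf * achan))
  k <- 1L
  for (f in seq_len(nframes)) {
    chunk <- c(as.vector(matrix(pos[f, , ], 4L, npts)),
               as.vector(t(an[((f - 1) * spf + 1):(f * spf), , drop = FALSE])))
    out[k:(k + length(chunk) - 1)] <- chunk
    k <- k + length(chunk)
  }
  w_f32(con, out)
  invisible(path)
}

r_i8 <- function(raw, at, n = 1, signed = TRUE) {
  readBin(raw[at:(at + n - 1)], "integer", n, size = 1, signed = signed)
}
r_i16 <- function(raw, at, n = 1) {
  readBin(raw[at:(at + 2 * n - 1)], "integer", n, size = 2, endian = "little")
}
r_f32 <- function(raw, at, n = 1) {
  readBin(raw[at:(at + 4 * n - 1)], "numeric", n, size = 4, endian = "little")
}

parse_c3d_params <- function(bytes, at) {
  proc <- r_i8(bytes, at + 3, signed = FALSE)
  if (proc != 84) {
    stop("unsupported C3D processor type ", proc, " (only Intel/84)",
         call. = FALSE)
  }
  pos <- at + 4
  groups <- list()   # id -> name
  params <- list()   # "GROUP:NAME" -> value
  repeat {
    nname <- r_i8(bytes, pos)
    if (nname == 0) break
    gid <- r_i8(bytes, pos + 1)
    name <- rawToChar(bytes[(pos + 2):(pos + 1 + abs(nname))])
    p <- pos + 2 + abs(nname)
    offset <- r_i16(bytes, p)
    nxt <- p + offset
    if (gid < 0) {
      groups[[as.character(-gid)]] <- name
    } else {
      type <- r_i8(bytes, p + 2)
      ndim <- r_i8(bytes, p + 3)
      dims <- if (ndim > 0) r_i8(bytes, p + 4, ndim, signed = FALSE) else integer(0)
      dat <- p + 4 + ndim
      count <- max(1L, prod(dims))
      val <- switch(as.character(type),
        `-1` = {
          s <- rawToChar(bytes[dat:(dat + count - 1)])
          if (length(dims) >= 2) {
            w <- dims[1]
            trimws(substring(s, seq(1, count, w), seq(w, count, w)))
          } else trimws(s)
        },
        `1` = r_i8(bytes, dat, count),
        `2` = r_i16(bytes, dat, count),
        `4` = r_f32(bytes, dat, count),
        stop("unknown C3D parameter type ", type, call. = FALSE))
      params[[paste0(gid, ":", name)]] <- val
    }
    if (offset == 0) break
    pos <- nxt
  }
  out <- list()
  for (key in names(params)) {
    gid <- sub(":.*", "", key)
    gname <- groups[[gid]]
    if (is.null(gname)) next
    out[[paste0(gname, ":", sub("^[^:]*:", "", key))]] <- params[[key]]
  }
  out
}

c3d_param <- function(params, key, default = NULL) {
  v <- params[[key]]
  if (is.null(v)) {
    if (is.null(default)) {
      stop("C3D parameter ", key, " missing; present: ",
           paste(names(params), collapse = ", "), call. = FALSE)
    }
    return(default)
  }
  v
}

#' Read a trial from a C3D file
#'
#' Supports little-endian files with floating-point point and analog data
#' (the layout [write_trial_c3d()] produces). Marker labels are normalized
#' through `alias_map`; point units "mm" are converted to metres. The six
#' analog channels are interpreted as plate1/plate2 Fx,Fy,Fz in file order
#' unless labels of the form `plateN_F[xyz]` identify them.
#'
#' @param path C3D file path.
#' @param alias_map optional named character vector, file label -> canonical.
#' @param meta metadata list merged into the trial.
#' @return a [trial()].
#' @export
read_trial_c3d <- function(path, alias_map = NULL, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 2 * BLOCK || r_i8(bytes, 2, signed = FALSE) != 80) {
    stop("not a C3D file (magic byte 0x50 absent at offset 1): ", path,
         call. = FALSE)
  }
  param_block <- r_i8(bytes, 1)
  npts <- r_i16(bytes, 3)
  tot_analog <- r_i16(bytes, 5)
  first_fr <- r_i16(bytes, 7)
  last_fr <- r_i16(bytes, 9)
  scale_hdr <- r_f32(bytes, 13)
  spf <- r_i16(bytes, 19)
  prate <- r_f32(bytes, 21)

  if (npts < 1) stop("C3D has no 3D point data: ", path, call. = FALSE)
  params <- parse_c3d_params(bytes, (param_block - 1) * BLOCK + 1)
  nframes <- last_fr - first_fr + 1L
  nframes <- c3d_param(params, "POINT:FRAMES", nframes)
  scale <- c3d_param(params, "POINT:SCALE", scale_hdr)
  if (scale >= 0) {
    stop("integer-scaled C3D point data not supported (POINT:SCALE >= 0)",
         call. = FALSE)
  }
  data_start <- c3d_param(params, "POINT:DATA_START", r_i16(bytes, 17))
  units <- c3d_param(params, "POINT:UNITS", "mm")
  plabels <- c3d_param(params, "POINT:LABELS",
                       sprintf("point_%02d", seq_len(npts)))
  achan <- c3d_param(params, "ANALOG:USED", 0L)
  if (achan < 6) {
    stop("C3D lacks the six force analog channels (ANALOG:USED = ", achan,
         "); analog labels present: ",
         paste(c3d_param(params, "ANALOG:LABELS", character(0)),
             collapse = ", "), call. = FALSE)
  }
  arate <- c3d_param(params, "ANALOG:RATE", prate * spf)
  alabels <- c3d_param(params, "ANALOG:LABELS",
                       sprintf("analog_%02d", seq_len(achan)))

  at <- (data_start - 1) * BLOCK + 1
  per_frame <- 4L * npts + spf * achan
  vals <- r_f32(bytes, at, per_frame * nframes)
  dim(vals) <- c(per_frame, nframes)
  pvals <- vals[seq_len(4L * npts), , drop = FALSE]
  avals <- vals[-seq_len(4L * npts), , drop = FALSE]

  scale_pos <- if (tolower(units) == "mm") 1e-3 else 1
  markers <- list()
  for (i in seq_len(npts)) {
    rows <- (i - 1) * 4 + 1:4
    xyz <- t(pvals[rows[1:3], , drop = FALSE]) * scale_pos
    occ <- pvals[rows[4], ] < 0
    xyz[occ, ] <- 0
    lab <- plabels[i]
    canon <- if (!is.null(alias_map) && lab %in% names(alias_map)) {
      unname(alias_map[[lab]])
    } else lab
    markers[[canon]] <- marker_trajectory(canon, xyz, prate, occ)
  }
  an <- matrix(as.vector(avals), nrow = achan)  # channel-major per subframe
  an <- t(an)
  want <- c(t(outer(c("plate1_F", "plate2_F"), c("x", "y", "z"), paste0)))
  idx <- match(want, alabels)
  if (anyNA(idx)) idx <- 1:6
  plates <- lapply(1:2, function(p) {
    force_channel(p, an[, idx[(p - 1) * 3 + 1]], an[, idx[(p - 1) * 3 + 2]],
                  an[, idx[(p - 1) * 3 + 3]], arate)
  })
  align_clocks(trial(markers, plates, meta))
}
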