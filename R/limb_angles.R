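#' Sagittal and coronal limb angles from cannon-bone orientation
#'
#' Because the heading of the horse is part of the orientation signal and no
#' absolute heading reference exists, the forward-swing (sagittal) direction
#' is determined for each stride individually: the rotation between the
#' orientations at hoof-off and the following hoof-on is de-twisted about the
#' vertical axis, and the remaining swing rotation's axis — horizontal, and
#' perpendicular to the sagittal plane — is the stride's sagittal axis. The
#' coronal axis is the sagittal axis rotated 90 degrees about vertical. Limb
#' angles are then per-sample swing-twist angles about these axes of the
#' orientation relative to the mid-stance orientation, so that both angles
#' are zero at mid-stance by construction.
#'
#' @name limb_angles
NULL

#' Rotation between the hoof-on and hoof-off orientations
#'
#' @param q_on Orientation at the hoof-on ending the swing phase.
#' @param q_off Orientation at the preceding hoof-off.
#' @return The quaternion `q_on x q_off*`.
#' @export
stride_rotation <- function(q_on, q_off) {
  quat_multiply(quat(q_on), quat_conjugate(quat(q_off)))
}

#' Per-stride sagittal and coronal axes
#'
#' De-twists the stride rotation about the vertical (z) axis and takes the
#' residual swing rotation's axis as the sagittal axis (normal of the
#' sagittal plane); the coronal axis is that axis rotated +90 degrees about z.
#'
#' @param qr Stride rotation from [stride_rotation()].
#' @param min_swing_deg Smallest usable swing angle; a near-pure-z rotation
#'   leaves the sagittal plane undefined and is an error.
#' @return List with unit 3-vectors `sagittal_axis` and `coronal_axis` (both
#'   horizontal).
#' @export
stride_axes <- function(qr, min_swing_deg = 1) {
  st <- swing_twist(quat(qr), c(0, 0, 1))
  sw <- st$swing
  ang <- 2 * acos(min(1, abs(sw[1, 1]))) * 180 / pi
  if (ang <= min_swing_deg) {
    stop("stride rotation has (near-)no sagittal swing; axis undefined")
  }
  v <- unname(sw[1, 2:4])
  v[3] <- 0  # numerically enforce horizontality (exact up to rounding already)
  v <- v / sqrt(sum(v^2))
  list(sagittal_axis = v,
       coronal_axis = c(-v[2], v[1], 0))  # +90 deg about z
}

#' Per-sample limb-angle signals
#'
#' @param qsig Limb orientation [quat_signal()] synchronized with `strides`.
#' @param strides A [stride_set()] for the same limb.
#' @param left_limb Mirror the coronal axis so that outward tilt (abduction)
#'   is positive on either body side; defaults from the stride set's limb
#'   label (LF/LH are left).
#' @param lowpass_cutoff Cutoff (Hz) for zero-phase smoothing of the angle
#'   signals, NULL to skip. After filtering each angle is re-anchored to be
#'   exactly zero at the mid-stance sample.
#' @param max_gap_fraction Strides with a larger fraction of gap samples are
#'   skipped and reported in the `skipped` attribute.
#' @return Object of class `limb_angle_signals`: data frame `samples` with
#'   columns `stride`, `time`, `sagittal`, `coronal` (degrees; sagittal
#'   positive = protraction, coronal positive = abduction), a per-stride
#'   `axes` data frame, and `skipped` stride indices.
#' @export
limb_angle_signals <- function(qsig, strides, left_limb = NULL,
                               lowpass_cutoff = 30, max_gap_fraction = 0.25) {
  stopifnot(inherits(qsig, "quat_signal"), inherits(strides, "stride_set"))
  if (is.null(left_limb)) left_limb <- strides$limb %in% c("LF", "LH")
  sdf <- strides$strides
  co <- if (!is.null(lowpass_cutoff)) {
    butter_coefs(4, lowpass_cutoff, qsig$fs, "low")
  }
  out <- vector("list", nrow(sdf))
  axes <- vector("list", nrow(sdf))
  skipped <- integer(0)
  tt <- qsig_time(qsig)
  for (i in seq_len(nrow(sdf))) {
    i_on <- ts_index(qsig, sdf$on[i])
    i_next <- ts_index(qsig, sdf$next_on[i])
    i_off <- ts_index(qsig, sdf$off[i])
    i_mid <- ts_index(qsig, midstance_time(sdf[i, ], qsig$fs, qsig$t0))
    idx <- i_on:i_next
    if (mean(qsig$gap[idx]) > max_gap_fraction ||
        qsig$gap[i_off] || qsig$gap[i_next] || qsig$gap[i_mid]) {
      skipped <- c(skipped, i)
      next
    }
    ax <- tryCatch(
      stride_axes(stride_rotation(qsig$q[i_next, ], qsig$q[i_off, ])),
      error = function(e) NULL
    )
    if (is.null(ax)) { skipped <- c(skipped, i); next }
    sag <- ax$sagittal_axis
    qseg <- qsig$q[idx, , drop = FALSE]
    gapi <- qsig$gap[idx]
    if (any(gapi)) {  # placeholder rows: carry the nearest valid sample
      src <- which(!gapi)
      near <- src[pmax(1, findInterval(which(gapi), src))]
      qseg[gapi, ] <- qseg[near, , drop = FALSE]
    }
    q_rm <- quat_multiply(qseg,
                          quat_conjugate(qsig$q[i_mid, , drop = FALSE]))
    sag_try <- twist_angle(swing_twist(q_rm, sag)$twist, sag)
    # orient the axis so the angle at hoof-on (protraction) is positive
    if (sag_try[length(sag_try)] < 0) {
      sag <- -sag
      sag_try <- -sag_try
    }
    cor <- c(-sag[2], sag[1], 0)
    if (left_limb) cor <- -cor
    cor_ang <- twist_angle(swing_twist(q_rm, cor)$twist, cor)
    sag_ang <- sag_try
    sag_ang[gapi] <- NA; cor_ang[gapi] <- NA
    if (!is.null(co) && length(idx) >= 13) {
      mid_rel <- i_mid - i_on + 1
      smooth <- function(x) {
        if (any(gapi)) {
          src <- which(!gapi)
          x[gapi] <- stats::approx(src, x[src], xout = which(gapi), rule = 2)$y
        }
        y <- zero_phase_filter(x, co$b, co$a,
                               padlen = max(12, ceiling(3 * qsig$fs / lowpass_cutoff)))
        y <- y - y[mid_rel]  # restore the exact mid-stance zero
        y[gapi] <- NA
        y
      }
      sag_ang <- smooth(sag_ang)
      cor_ang <- smooth(cor_ang)
    }
    out[[i]] <- data.frame(stride = i, time = tt[idx],
                           sagittal = sag_ang, coronal = cor_ang)
    axes[[i]] <- data.frame(stride = i,
                            sag_x = sag[1], sag_y = sag[2], sag_z = sag[3],
                            cor_x = cor[1], cor_y = cor[2], cor_z = cor[3])
  }
  structure(list(samples = do.call(rbind, out),
                 axes = do.call(rbind, axes),
                 skipped = skipped,
                 limb = strides$limb, fs = qsig$fs),
            class = "limb_angle_signals")
}

#' @exportS3Method base::print
print.limb_angle_signals <- function(x, ...) {
  ns <- if (is.null(x$samples)) 0L else length(unique(x$samples$stride))
  cat(sprintf("<limb_angle_signals> %s: %d stride(s), %d skipped\n",
              x$limb, ns, length(x$skipped)))
  invisible(x)
}

#' Per-stride limb-angle parameters
#'
#' Protraction and retraction are the sagittal angles at the hoof-on and
#' hoof-off moments; abduction and adduction are the coronal extrema over the
#' stride; the ranges of motion are the spans between the respective extremes.
#'
#' @param sig A [limb_angle_signals()].
#' @param strides The matching [stride_set()].
#' @return Data frame of class `limb_angle_result` with one row per retained
#'   stride: `limb`, `stride`, `protraction`, `retraction`, `abduction`,
#'   `adduction`, `sagittal_rom`, `coronal_rom` (degrees).
#' @export
extract_limb_parameters <- function(sig, strides) {
  stopifnot(inherits(sig, "limb_angle_signals"), inherits(strides, "stride_set"))
  sdf <- strides$strides
  res <- NULL
  if (!is.null(sig$samples)) {
    for (i in unique(sig$samples$stride)) {
      seg <- sig$samples[sig$samples$stride == i, ]
      i_off <- which.min(abs(seg$time - sdf$off[i]))
      pro <- seg$sagittal[nrow(seg)]       # hoof-on ends the stride's swing
      ret <- seg$sagittal[i_off]
      abd <- suppressWarnings(max(seg$coronal, na.rm = TRUE))
      add <- suppressWarnings(min(seg$coronal, na.rm = TRUE))
      if (!is.finite(abd) || !is.finite(add) || is.na(pro) || is.na(ret)) next
      res <- rbind(res, data.frame(
        limb = sig$limb, stride = i,
        protraction = pro, retraction = ret,
        abduction = abd, adduction = add,
        sagittal_rom = abs(pro - ret),
        coronal_rom = abd - add
      ))
    }
  }
  if (is.null(res)) {
    res <- data.frame(limb = character(0), stride = integer(0),
                      protraction = numeric(0), retraction = numeric(0),
                      abduction = numeric(0), adduction = numeric(0),
                      sagittal_rom = numeric(0), coronal_rom = numeric(0))
  }
  class(res) <- c("limb_angle_result", "data.frame")
  res
}

#' Write per-stride limb parameters as a tab-separated table
#'
#' @param res A `limb_angle_result`.
#' @param path Output file path.
#' @export
write_limb_parameters <- function(res, path) {
  df <- data.frame(limb = res$limb, stride_index = res$stride,
                   protraction_deg = res$protraction,
                   retraction_deg = res$retraction,
                   abduction_deg = res$abduction,
                   adduction_deg = res$adduction,
                   sag_rom_deg = res$sagittal_rom,
                   cor_rom_deg = res$coronal_rom)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
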