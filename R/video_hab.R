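#' Camera frame
#'
#' An 8-bit RGB frame from a shore-mounted monitoring camera, stored as an
#' H x W x 3 numeric array on the 0--255 scale with device id and capture
#' time attached.
#'
#' @param pixels H x W x 3 array, values in \[0, 255\]; H, W >= 16.
#' @param device_id camera identifier.
#' @param timestamp capture time (POSIXct or ISO-8601 text).
#' @return an object of class `camera_frame`.
#' @export
camera_frame <- function(pixels, device_id = "dev", timestamp = Sys.time()) {
  pixels <- unclass(pixels)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("`pixels` must be H x W x 3")
  if (d[1] < 16L || d[2] < 16L) stop("frame must be at least 16 x 16")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  structure(list(pixels = pixels, device_id = device_id,
                 timestamp = as_utc(timestamp)),
            class = "camera_frame")
}

#' @export
print.camera_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<camera_frame> %s @ %s | %d x %d px\n", x$device_id,
              format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ"), d[1], d[2]))
  invisible(x)
}

#' Read / write frames as PNG
#'
#' Filenames follow `<device>_<ISO timestamp>.png`; `read_frame_png` recovers
#' device and time from the name when not supplied.
#' @param path PNG path.
#' @param frame a [camera_frame()].
#' @export
read_frame_png <- function(path, device_id = NULL, timestamp = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  a <- a[, , 1:3, drop = FALSE] * 255
  if (is.null(device_id) || is.null(timestamp)) {
    base <- sub("\\.png$", "", basename(path))
    parts <- regmatches(base, regexec("^(.*)_([0-9T:.Z-]+)$", base))[[1]]
    if (length(parts) == 3L) {
      if (is.null(device_id)) device_id <- parts[2]
      if (is.null(timestamp)) timestamp <- gsub("-(\\d{2})-(\\d{2})Z$", ":\\1:\\2Z", parts[3])
    }
  }
  camera_frame(a, device_id %||% "dev", timestamp %||% Sys.time())
}

#' @rdname read_frame_png
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' Frame preprocessing: centre-crop, resize, normalise
#'
#' Standard conditioning before segmentation: centre-crop to the target aspect
#' ratio, bilinear-resize to the target size, and optionally rescale channels
#' to \[0, 1\]. A frame already at the target size with normalisation off
#' passes through bit-identically.
#'
#' @param frame a [camera_frame()].
#' @param target_size length-2 integer (height, width), each >= 16.
#' @param normalize if TRUE, divide channels by 255.
#' @return a `camera_frame` (pixels in \[0,1\] when normalised).
#' @export
preprocess_frame <- function(frame, target_size = c(64L, 64L), normalize = FALSE) {
  stopifnot(inherits(frame, "camera_frame"))
  th <- as.integer(target_size[1]); tw <- as.integer(target_size[2])
  if (th < 16L || tw < 16L) stop("target size must be at least 16 x 16")
  px <- frame$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < th && w < tw && (h < 16L || w < 16L))
    stop("frame smaller than the minimum size")
  aspect <- tw / th
  if (w / h > aspect) {          # too wide: crop columns
    cw <- max(1L, round(h * aspect))
    off <- floor((w - cw) / 2)
    px <- px[, (off + 1):(off + cw), , drop = FALSE]
  } else if (w / h < aspect) {   # too tall: crop rows
    ch <- max(1L, round(w / aspect))
    off <- floor((h - ch) / 2)
    px <- px[(off + 1):(off + ch), , , drop = FALSE]
  }
  if (!identical(dim(px)[1:2], c(th, tw))) px <- resize_bilinear(px, th, tw)
  out <- frame
  out$pixels <- if (normalize) px / 255 else px
  out
}

# bilinear resample of an H x W x C array to h2 x w2
resize_bilinear <- function(a, h2, w2) {
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  ty <- pmin(pmax((seq_len(h2) - 0.5) * h / h2 - 0.5, 0), h - 1)
  tx <- pmin(pmax((seq_len(w2) - 0.5) * w / w2 - 0.5, 0), w - 1)
  y0 <- pmin(floor(ty) + 1, h); y1 <- pmin(y0 + 1, h); fy <- ty - (y0 - 1)
  x0 <- pmin(floor(tx) + 1, w); x1 <- pmin(x0 + 1, w); fx <- tx - (x0 - 1)
  out <- array(0, c(h2, w2, nc))
  wy0 <- (1 - fy); wy1 <- fy
  wx0 <- (1 - fx); wx1 <- fx
  for (k in seq_len(nc)) {
    m <- a[, , k]
    out[, , k] <- (wy0 %o% wx0) * m[y0, x0, drop = FALSE] +
      (wy0 %o% wx1) * m[y0, x1, drop = FALSE] +
      (wy1 %o% wx0) * m[y1, x0, drop = FALSE] +
      (wy1 %o% wx1) * m[y1, x1, drop = FALSE]
  }
  out
}

#' Pluggable segmentation contract
#'
#' A segmenter is a named, versioned predictor mapping a frame to a logical
#' HAB mask of the same height and width, deterministic given fixed parameters.
#' Any function honouring that contract can drive the monitoring chain; the
#' package ships a colour-index baseline ([baseline_segmenter()]) and a
#' trainable pixel classifier ([train_segmenter()]).
#'
#' @param name,version identification recorded in outputs.
#' @param predict_fun function(pixels_HxWx3_0_255, params) -> logical matrix.
#' @param params parameter list passed to `predict_fun`.
#' @return an object of class `hab_segmenter`; use [predict()] on frames.
#' @export
hab_segmenter <- function(name, version, predict_fun, params = list()) {
  stopifnot(is.function(predict_fun))
  structure(list(name = name, version = version, predict_fun = predict_fun,
                 params = params),
            class = "hab_segmenter")
}

#' @export
print.hab_segmenter <- function(x, ...) {
  cat(sprintf("<hab_segmenter> %s v%s\n", x$name, x$version))
  invisible(x)
}

#' @export
predict.hab_segmenter <- function(object, frame, ...) {
  px <- if (inherits(frame, "camera_frame")) frame$pixels else unclass(frame)
  if (max(px) <= 1) px <- px * 255   # accept normalised frames
  m <- object$predict_fun(px, object$params)
  if (!is.logical(m) || !identical(dim(m), dim(px)[1:2]))
    stop("segmenter returned a mask of the wrong shape")
  m
}

#' Green-excess colour-index baseline segmenter
#'
#' Classifies a pixel as HAB when its green excess `G - (R + B) / 2` exceeds a
#' threshold (0--255 scale). Surface cyanobacterial scum is strongly
#' green-dominant against blue-grey water, making this simple index a strong
#' deterministic reference predictor.
#'
#' @param threshold green-excess threshold in 8-bit counts (default 20).
#' @return a [hab_segmenter()].
#' @export
baseline_segmenter <- function(threshold = 20) {
  hab_segmenter(
    "green-excess baseline", "1.0",
    function(px, params) {
      px[, , 2] - (px[, , 1] + px[, , 3]) / 2 > params$threshold
    },
    params = list(threshold = threshold)
  )
}

#' Coverage ratio of a segmentation mask
#'
#' The nearshore HAB statistic: the fraction of frame pixels classified as
#' HAB, in \[0, 1\].
#'
#' @param mask logical matrix (TRUE = HAB pixel).
#' @param device_id,timestamp carried into the record.
#' @return one-row data frame: `device_id`, `timestamp`, `ratio`,
#'   `hab_pixels`, `total_pixels`.
#' @export
coverage_ratio <- function(mask, device_id = "dev", timestamp = Sys.time()) {
  if (!is.logical(mask)) mask <- mask > 0
  n <- length(mask)
  if (n == 0L) stop("zero-size mask")
  k <- sum(mask)
  data.frame(device_id = device_id,
             timestamp = format(as_utc(timestamp), "%Y-%m-%dT%H:%M:%SZ"),
             ratio = k / n, hab_pixels = k, total_pixels = n,
             stringsAsFactors = FALSE)
}

#' Pixelwise confusion counts
#'
#' Tallies TP (HAB pixels correctly identified), FP (HAB-free pixels called
#' HAB), FN (HAB pixels missed) and TN between a predicted and a reference
#' mask. TN is not used by the F-score but is kept so the four counts always
#' sum to the pixel count.
#'
#' @param pred,truth logical matrices of identical shape.
#' @return list with integer fields TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth masks differ in shape")
  pred <- as.logical(pred); truth <- as.logical(truth)
  list(TP = sum(pred & truth), FP = sum(pred & !truth),
       FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

#' Precision, recall and F-score from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R). When there are no positives
#' anywhere (TP+FP = 0 and TP+FN = 0) the F-score is defined as 0 with a
#' warning; when only one denominator vanishes the corresponding rate is 0.
#'
#' @param counts list with TP, FP, FN (as from [confusion_counts()]).
#' @return named numeric vector c(P, R, F).
#' @export
f_score <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP == 0 && TP + FN == 0) {
    warning("no positive pixels in prediction or truth; F-score defined as 0")
    return(c(P = 0, R = 0, F = 0))
  }
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F = F)
}

#' Train a pixel-colour segmenter
#'
#' Fits a logistic classifier on per-pixel colour features (scaled R, G, B and
#' green excess) by full-batch gradient descent with backtracking line search,
#' so the recorded training loss (binary cross-entropy) is non-increasing by
#' construction and the whole procedure is deterministic under a fixed seed
#' (the seed drives only the train/validation split and pixel subsampling).
#' The result honours the [hab_segmenter()] contract and reports per-epoch
#' losses plus the validation F-score.
#'
#' @param pairs list of `list(frame = camera_frame, truth = logical matrix)`.
#' @param hyperparams list: `epochs` (default 30), `lr` (initial step, 5),
#'   `pixels_per_frame` subsample size (2000), `val_frac` (0.25).
#' @param seed integer seed.
#' @return a `hab_segmenter` with attributes `losses` (numeric per epoch) and
#'   `validation_f` (scalar, `NA` if no validation frames had positives).
#' @export
train_segmenter <- function(pairs, hyperparams = list(), seed = 1) {
  if (!length(pairs)) stop("empty training set")
  if (length(pairs) < 2L) stop("need at least 2 frame/mask pairs")
  hp <- utils::modifyList(
    list(epochs = 30L, lr = 5, pixels_per_frame = 2000L, val_frac = 0.25),
    hyperparams)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  n <- length(pairs)
  n_val <- max(1L, floor(hp$val_frac * n))
  idx <- sample.int(n)
  val_i <- idx[seq_len(n_val)]
  trn_i <- idx[-seq_len(n_val)]

  feat <- function(px) {
    if (max(px) > 1) px <- px / 255
    r <- as.vector(px[, , 1]); g <- as.vector(px[, , 2]); b <- as.vector(px[, , 3])
    cbind(1, r, g, b, g - (r + b) / 2)
  }
  X <- NULL; y <- NULL
  for (i in trn_i) {
    px <- pairs[[i]]$frame$pixels
    f <- feat(px)
    lab <- as.numeric(pairs[[i]]$truth)
    take <- sample.int(nrow(f), min(hp$pixels_per_frame, nrow(f)))
    X <- rbind(X, f[take, , drop = FALSE]); y <- c(y, lab[take])
  }

  if (all(y == 0)) {
    warning("all training pixels are background; returning constant all-false segmenter")
    seg <- hab_segmenter("constant background", "1.0",
                         function(px, params) {
                           matrix(FALSE, dim(px)[1], dim(px)[2])
                         })
    attr(seg, "losses") <- rep(NA_real_, 0)
    attr(seg, "validation_f") <- NA_real_
    return(seg)
  }

  bce <- function(w) {
    p <- 1 / (1 + exp(-drop(X %*% w)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  w <- rep(0, ncol(X))
  loss <- bce(w)
  losses <- numeric(hp$epochs)
  for (e in seq_len(hp$epochs)) {
    p <- 1 / (1 + exp(-drop(X %*% w)))
    g <- drop(crossprod(X, p - y)) / nrow(X)
    step <- hp$lr
    repeat {                      # backtracking: never accept an uphill step
      cand <- w - step * g
      l2 <- bce(cand)
      if (l2 <= loss || step < 1e-10) break
      step <- step / 2
    }
    if (l2 <= loss) { w <- cand; loss <- l2 }
    losses[e] <- loss
  }

  seg <- hab_segmenter(
    "trained pixel-colour classifier", "1.0",
    function(px, params) {
      if (max(px) > 1) px <- px / 255
      r <- as.vector(px[, , 1]); g <- as.vector(px[, , 2]); b <- as.vector(px[, , 3])
      f <- cbind(1, r, g, b, g - (r + b) / 2)
      matrix(drop(f %*% params$w) > 0, dim(px)[1], dim(px)[2])
    },
    params = list(w = w)
  )
  cc <- list(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in val_i) {
    m <- predict(seg, pairs[[i]]$frame)
    ci <- confusion_counts(m, pairs[[i]]$truth)
    cc <- Map(`+`, cc, ci)
  }
  attr(seg, "losses") <- losses
  attr(seg, "validation_f") <- if (cc$TP + cc$FP == 0 && cc$TP + cc$FN == 0)
    NA_real_ else unname(f_score(cc)["F"])
  seg
}

#' Periodic coverage monitoring over a frame stream
#'
#' Walks a time-ordered sequence of frames, samples one frame per period, and
#' emits a coverage record for each sampled frame. Sampling is restricted to a
#' daily observation window (default 08:00--18:00, matching daylight camera
#' operation); frames outside the window are skipped without consuming the
#' sampling clock.
#'
#' @param frames list of [camera_frame()], timestamps non-decreasing.
#' @param segmenter a [hab_segmenter()].
#' @param period_s sampling period in seconds (default 1).
#' @param window_hours length-2 numeric, daily window \[start, end) in UTC
#'   hours. Default c(8, 18).
#' @return data frame of coverage records (possibly 0 rows).
#' @export
monitor_stream <- function(frames, segmenter, period_s = 1,
                           window_hours = c(8, 18)) {
  stopifnot(length(frames) > 0, inherits(segmenter, "hab_segmenter"))
  times <- as_utc(do.call(c, lapply(frames, `[[`, "timestamp")))
  if (is.unsorted(as.numeric(times)))
    stop("frame timestamps are not time-ordered")
  hour <- as.numeric(format(times, "%H")) + as.numeric(format(times, "%M")) / 60
  out <- list()
  last <- -Inf
  for (i in seq_along(frames)) {
    if (hour[i] < window_hours[1] || hour[i] >= window_hours[2]) next
    if (as.numeric(times[i]) - last < period_s) next
    last <- as.numeric(times[i])
    m <- predict(segmenter, frames[[i]])
    out[[length(out) + 1L]] <-
      coverage_ratio(m, frames[[i]]$device_id, frames[[i]]$timestamp)
  }
  if (!length(out))
    return(data.frame(device_id = character(), timestamp = character(),
                      ratio = numeric(), hab_pixels = integer(),
                      total_pixels = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
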