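#' Fit a graph-prolongation convolutional network (or baseline) to frame data
#'
#' The package's central fitting function.  Takes a simulated frame dataset,
#' splits it into training and validation frames with the run-level seed,
#' normalizes by training-split statistics, builds the requested model and
#' trains it with mean-squared-error loss at the fine scale.
#'
#' @param data An `mt_dataset` (from [generate_dataset()] /
#'   [generate_dataset_desk()]), or a list with `x`
#'   (`frames x nodes x features`) and `y` (`frames x nodes`).
#' @param preset A [model_preset()] name (e.g. `"3-level A-GPCN"`), or a list
#'   with fields `kind`, `members` (and `radii` / `levels`) for custom
#'   architectures.
#' @param hierarchy A `gpcn_hierarchy` for multiscale kinds; defaults to the
#'   desk-scale microtubule hierarchy when the data's fine size matches it.
#' @param graph Fine graph or Laplacian for flat kinds; defaults to the
#'   hierarchy's fine level.
#' @param schedule A [schedule_spec()].
#' @param config A [train_config()]; its `seed` controls the split, the
#'   initialization, and batch order.
#' @param scale Preset scale passed to [model_preset()] when `preset` is a
#'   name.
#' @return An object of class `gpcn_fit` with the trained `model`, the
#'   training `history`, the normalization `stats`, split indices, and the
#'   matched call.  Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `fitted`, `residuals`.
#' @examples
#' \donttest{
#' ds <- generate_dataset_desk(seed = 1)
#' fit <- gpcn_fit(ds, "3-level A-GPCN",
#'                 config = train_config(epochs = 5, seed = 1))
#' summary(fit)
#' }
#' @export
gpcn_fit <- function(data, preset = "3-level A-GPCN", hierarchy = NULL,
                     graph = NULL, schedule = schedule_spec("joint"),
                     config = train_config(), scale = "desk") {
  cl <- match.call()
  spec <- if (is.character(preset)) model_preset(preset, scale) else preset
  x <- data$x; y <- data$y
  n_nodes <- dim(x)[2]

  if (spec$kind %in% c("gpcn", "agpcn", "diffpool")) {
    if (is.null(hierarchy)) {
      hscale <- if (n_nodes == 624) "paper" else if (n_nodes == 156) "desk"
                else stop("no default hierarchy for ", n_nodes,
                          " nodes; pass `hierarchy`")
      hierarchy <- microtubule_hierarchy(hscale,
                                         levels = spec$levels %||% 3)
    }
    if (!is.null(spec$levels) && length(hierarchy$sizes) != spec$levels) {
      hierarchy <- build_hierarchy(hierarchy$graphs[seq_len(spec$levels)])
    }
    if (hierarchy$sizes[1] != n_nodes)
      stop("hierarchy fine level (", hierarchy$sizes[1],
           ") does not match the data (", n_nodes, " nodes)")
  } else if (is.null(graph)) {
    graph <- if (!is.null(hierarchy)) hierarchy$laplacians[[1]]
             else laplacian(build_tube_graph(guess_tube_spec(n_nodes)))
  }

  # split, normalize (training statistics only)
  set.seed(config$seed)
  nf <- dim(x)[1]
  nval <- max(1L, round(config$validation_fraction * nf))
  val_idx <- sort(sample(nf, nval))
  tr_idx <- setdiff(seq_len(nf), val_idx)
  stats <- suppressWarnings(
    normalize_stats(x[tr_idx, , , drop = FALSE], y[tr_idx, , drop = FALSE]))
  ntr <- apply_normalization(x[tr_idx, , , drop = FALSE],
                             y[tr_idx, , drop = FALSE], stats)
  nva <- apply_normalization(x[val_idx, , , drop = FALSE],
                             y[val_idx, , drop = FALSE], stats)

  # members listed coarse-last in presets for multiscale kinds: reorder so
  # member 1 is the fine level (presets already store fine-first)
  model <- gcn_model(spec$kind, spec$members, hierarchy = hierarchy,
                     graph = graph, radii = spec$radii,
                     input_dim = dim(x)[3], seed = config$seed)
  out <- train_model(model, ntr$x, ntr$y, nva$x, nva$y, config, schedule)

  structure(list(model = out$model, history = out$history, stats = stats,
                 train_idx = tr_idx, val_idx = val_idx, config = config,
                 schedule = schedule,
                 preset = if (is.character(preset)) preset else spec$kind,
                 data = data, call = cl),
            class = "gpcn_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_tube_spec <- function(n_nodes) {
  if (n_nodes %% 13 != 0)
    stop("cannot infer a 13-wide tube from ", n_nodes, " nodes; pass `graph`")
  tube_spec(n_nodes / 13, 13, 3)
}

#' @export
print.gpcn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("%s fit (%s schedule): %d epochs\n", x$preset,
              x$schedule$kind, nrow(h)))
  cat(sprintf("  final val NMSE %.4g | min val NMSE %.4g | %.3g ledger FLOPs\n",
              h$val_nmse[nrow(h)], min(h$min_val_nmse),
              h$cum_flops[nrow(h)]))
  invisible(x)
}

#' @export
summary.gpcn_fit <- function(object, ...) {
  h <- object$history
  structure(list(preset = object$preset, kind = object$model$kind,
                 epochs = nrow(h), min_val_nmse = min(h$min_val_nmse),
                 final_val_nmse = h$val_nmse[nrow(h)],
                 final_train_mse = h$train_mse[nrow(h)],
                 cum_flops = h$cum_flops[nrow(h)],
                 n_parameters = sum(vapply(flatten_params(object$model),
                                           length, 1)),
                 sizes = vapply(object$model$Z, nrow, 1L)),
            class = "summary.gpcn_fit")
}

#' @export
print.summary.gpcn_fit <- function(x, ...) {
  cat(sprintf("%s (%s), levels %s, %d parameters\n", x$preset, x$kind,
              paste(x$sizes, collapse = "/"), x$n_parameters))
  cat(sprintf("  %d epochs, min val NMSE %.4g, final val NMSE %.4g\n",
              x$epochs, x$min_val_nmse, x$final_val_nmse))
  cat(sprintf("  final train MSE %.4g, cumulative ledger FLOPs %.4g\n",
              x$final_train_mse, x$cum_flops))
  invisible(x)
}

#' @export
coef.gpcn_fit <- function(object, ...) flatten_params(object$model)

#' Predict per-node energies for new frames
#'
#' @param object A `gpcn_fit`.
#' @param newdata Input tensor `frames x nodes x features` (raw units), a
#'   single `nodes x features` matrix, or an `mt_dataset`; defaults to the
#'   fit's validation frames.
#' @param denormalize Return energies in the data's original units (default)
#'   or in normalized space.
#' @param ... Unused.
#' @return Matrix `frames x nodes` of predicted per-node energies.
#' @export
predict.gpcn_fit <- function(object, newdata = NULL, denormalize = TRUE, ...) {
  x <- if (is.null(newdata))
    object$data$x[object$val_idx, , , drop = FALSE]
  else if (inherits(newdata, "mt_dataset")) newdata$x
  else if (length(dim(newdata)) == 2)
    array(newdata, c(1, dim(newdata)))
  else newdata
  xn <- apply_normalization(x = x, stats = object$stats)$x
  pred <- model_predict(object$model, xn)
  if (denormalize)
    pred <- apply_normalization(y = pred, stats = object$stats,
                                invert = TRUE)$y
  pred
}

#' @export
fitted.gpcn_fit <- function(object, ...) {
  predict(object, object$data$x[object$train_idx, , , drop = FALSE], ...)
}

#' @export
residuals.gpcn_fit <- function(object, ...) {
  object$data$y[object$train_idx, , drop = FALSE] - fitted(object)
}

#' Plot training progress: running-minimum validation NMSE versus ledger FLOPs
#' @param x A `gpcn_fit` (or several, passed via `...`, drawn for comparison).
#' @param ... Further `gpcn_fit`s or graphical arguments.
#' @export
plot.gpcn_fit <- function(x, ...) {
  dots <- list(...)
  fits <- c(list(x), Filter(function(d) inherits(d, "gpcn_fit"), dots))
  cols <- grDevices::hcl.colors(max(3, length(fits)), "Dark 3")
  xr <- range(unlist(lapply(fits, function(f) f$history$cum_flops)))
  yr <- range(unlist(lapply(fits, function(f) f$history$min_val_nmse)))
  graphics::plot(NA, xlim = xr, ylim = yr, log = "y",
                 xlab = "cumulative ledger FLOPs",
                 ylab = "min validation NMSE",
                 main = "training efficiency")
  for (i in seq_along(fits))
    graphics::lines(fits[[i]]$history$cum_flops,
                    fits[[i]]$history$min_val_nmse, col = cols[i], lwd = 2)
  graphics::legend("topright", legend = vapply(fits, function(f)
    paste(f$preset, f$schedule$kind), ""), col = cols[seq_along(fits)],
    lwd = 2, bty = "n")
  invisible(x)
}
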