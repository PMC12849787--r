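#' Pipeline configuration
#'
#' All tunable settings of the pipeline in one validated object. Defaults
#' follow the training protocol the model is designed for: 1-s windows at
#' overlap 0.5, ten folds, Adam at learning rate 0.001 for 100 epochs with
#' batch size 64, dropout 0.5, focal loss with `gamma = 2`, `alpha = 0.25`,
#' two 8-head graph-attention layers and an L = 4 Transformer.
#'
#' @param montage montage preset name or `NULL` to keep channels as-is.
#' @param band_lo,band_hi bandpass edges (Hz).
#' @param filter_order bandpass Butterworth design order.
#' @param window_s,overlap sliding-window length (s) and overlap fraction.
#' @param label_threshold minimum overlap fraction for a seizure window label.
#' @param tau correlation threshold for graph edges, in (0, 1).
#' @param mode ablation mode: `"combined"`, `"gat_only"` or
#'   `"transformer_only"`.
#' @param n_seq windows per classification sample (Transformer tokens).
#' @param gat_hidden,gat_out per-head output dims of the two GAT layers.
#' @param gat_heads attention heads per GAT layer.
#' @param negative_slope LeakyReLU slope in attention scores.
#' @param activation GAT output nonlinearity (`"elu"`, `"relu"`,
#'   `"identity"`).
#' @param D,t_heads,mlp_hidden,L Transformer embedding dim, heads, MLP width
#'   and depth.
#' @param dropout dropout rate applied after each layer during training.
#' @param lr,epochs,batch_size Adam learning rate, epochs, batch size.
#' @param focal_alpha,focal_gamma focal-loss parameters.
#' @param n_folds cross-validation folds.
#' @param fold_method `"block"` (time-contiguous per class, the default;
#'   avoids overlapping windows straddling folds) or `"random"`.
#' @param seed integer seed driving fold assignment, balancing, parameter
#'   initialization, shuffling and dropout.
#' @return a validated `gatformer_config` list.
#' @export
gatformer_config <- function(montage = NULL, band_lo = 0.5, band_hi = 48,
                             filter_order = 6, window_s = 1.0, overlap = 0.5,
                             label_threshold = 0.5, tau = 0.3,
                             mode = "combined", n_seq = 8,
                             gat_hidden = 64, gat_out = 64, gat_heads = 8,
                             negative_slope = 0.2, activation = "elu",
                             D = 128, t_heads = 4, mlp_hidden = 4 * D, L = 4,
                             dropout = 0.5, lr = 0.001, epochs = 100,
                             batch_size = 64, focal_alpha = 0.25,
                             focal_gamma = 2, n_folds = 10,
                             fold_method = "block", seed = 1L) {
  cfg <- mget(names(formals()))
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
  structure(cfg, class = "gatformer_config")
}

validate_config <- function(cfg) {
  ok <- function(cond, key, what) {
    if (!cond)
      gf_stop("gatformer_config_error", "invalid config key `%s`: %s", key, what)
  }
  ok(is.null(cfg$montage) || cfg$montage %in% c("chbmit16", "tuh20"),
     "montage", "must be NULL, 'chbmit16' or 'tuh20'")
  ok(is_scalar(cfg$band_lo) && cfg$band_lo > 0, "band_lo", "must be > 0")
  ok(is_scalar(cfg$band_hi) && cfg$band_hi > cfg$band_lo, "band_hi",
     "must exceed band_lo")
  ok(is_count(cfg$filter_order), "filter_order",
     "must be a positive integer")
  ok(is_scalar(cfg$window_s) && cfg$window_s > 0, "window_s", "must be > 0")
  ok(is_scalar(cfg$overlap) && cfg$overlap >= 0 && cfg$overlap < 1,
     "overlap", "must be in [0, 1)")
  ok(is_scalar(cfg$label_threshold) && cfg$label_threshold > 0 &&
       cfg$label_threshold <= 1, "label_threshold", "must be in (0, 1]")
  ok(is_scalar(cfg$tau) && cfg$tau > 0 && cfg$tau < 1, "tau",
     "must be in (0, 1)")
  ok(cfg$mode %in% c("combined", "gat_only", "transformer_only"), "mode",
     "must be one of combined / gat_only / transformer_only")
  ok(is_count(cfg$n_seq), "n_seq", "must be a positive integer")
  ok(is_count(cfg$gat_hidden) && is_count(cfg$gat_out) &&
       is_count(cfg$gat_heads), "gat_hidden/gat_out/gat_heads",
     "must be positive integers")
  ok(is_scalar(cfg$negative_slope) && cfg$negative_slope >= 0,
     "negative_slope", "must be >= 0")
  ok(cfg$activation %in% c("elu", "relu", "identity"), "activation",
     "must be elu / relu / identity")
  ok(is_count(cfg$D) && cfg$D %% 2 == 0, "D", "must be a positive even integer")
  ok(is_count(cfg$t_heads) && cfg$D %% cfg$t_heads == 0, "t_heads",
     "must divide D")
  ok(is_count(cfg$mlp_hidden), "mlp_hidden", "must be a positive integer")
  ok(is_count(cfg$L), "L", "must be a positive integer")
  ok(is_scalar(cfg$dropout) && cfg$dropout >= 0 && cfg$dropout < 1,
     "dropout", "must be in [0, 1)")
  ok(is_scalar(cfg$lr) && cfg$lr > 0, "lr", "must be > 0")
  ok(is.numeric(cfg$epochs) && length(cfg$epochs) == 1 && cfg$epochs >= 0 &&
       cfg$epochs == as.integer(cfg$epochs), "epochs",
     "must be a nonnegative integer")
  ok(is_count(cfg$batch_size), "batch_size", "must be a positive integer")
  ok(is_scalar(cfg$focal_alpha) && cfg$focal_alpha > 0 && cfg$focal_alpha < 1,
     "focal_alpha", "must be in (0, 1)")
  ok(is_scalar(cfg$focal_gamma) && cfg$focal_gamma >= 0, "focal_gamma",
     "must be >= 0")
  ok(is_count(cfg$n_folds) && cfg$n_folds >= 2, "n_folds", "must be >= 2")
  ok(cfg$fold_method %in% c("block", "random"), "fold_method",
     "must be 'block' or 'random'")
  invisible(cfg)
}

#' @export
print.gatformer_config <- function(x, ...) {
  cat("<gatformer_config>\n")
  cat(sprintf("  windows: %.2g s, overlap %.2g; band %g-%g Hz; tau %.2g\n",
              x$window_s, x$overlap, x$band_lo, x$band_hi, x$tau))
  cat(sprintf("  model: %s, n_seq %d, GAT %dx%d heads -> %d, D %d, L %d\n",
              x$mode, x$n_seq, 2L, x$gat_heads, x$gat_out, x$D, x$L))
  cat(sprintf("  training: lr %g, %d epochs, batch %d, dropout %g, focal(%g, %g), %d folds (%s), seed %d\n",
              x$lr, x$epochs, x$batch_size, x$dropout, x$focal_alpha,
              x$focal_gamma, x$n_folds, x$fold_method, x$seed))
  invisible(x)
}

#' Load a configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected by name; value
#' errors name the offending key. An empty file yields the pure defaults.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return a [gatformer_config()].
#' @export
load_config <- function(path = NULL) {
  over <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      gf_stop("gatformer_io_error", "config file '%s' not found", path)
    over <- yaml::read_yaml(path) %||% list()
  }
  known <- names(formals(gatformer_config))
  bad <- setdiff(names(over), known)
  if (length(bad))
    gf_stop("gatformer_config_error", "unknown config key(s): %s",
            paste(bad, collapse = ", "))
  do.call(gatformer_config, over)
}
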