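#' The four architecture ablation variants
#'
#' `"resnet18"` (plain residual baseline), `"+cbam"` (adds attention),
#' `"+cbam+dsc"` (adds depthwise separability), `"full"` (adds the
#' multi-scale dilated stem).
#'
#' @format Character vector of length 4.
#' @export
ABLATION_VARIANTS <- c("resnet18", "+cbam", "+cbam+dsc", "full")

variant_flags <- function(variant) {
  switch(variant,
    "resnet18" = list(use_msdc = FALSE, use_dsc = FALSE, use_cbam = FALSE),
    "+cbam" = list(use_msdc = FALSE, use_dsc = FALSE, use_cbam = TRUE),
    "+cbam+dsc" = list(use_msdc = FALSE, use_dsc = TRUE, use_cbam = TRUE),
    "full" = list(use_msdc = TRUE, use_dsc = TRUE, use_cbam = TRUE),
    stop("unknown ablation variant: '", variant, "'; expected one of ",
         paste(ABLATION_VARIANTS, collapse = ", ")))
}

#' Run one ablation variant
#'
#' Maps the variant name onto the architecture flags (residual baseline,
#' + attention, + depthwise separability, full model with the multi-scale
#' stem), counts its parameters, and — when data are supplied — trains and
#' evaluates it by cross-validation, emitting accuracy, kappa, macro-F1 and
#' per-class F1 alongside the parameter count in millions.
#'
#' @param variant One of `"resnet18"`, `"+cbam"`, `"+cbam+dsc"`, `"full"`.
#' @param bundle Optional labeled `lmc_epoch_bundle`; without it only the
#'   architecture columns are filled.
#' @param model_args Named overrides passed to [model_config()] (e.g.
#'   reduced `stage_widths` for a quick run).
#' @param train_cfg A [train_config()].
#' @param by Cross-validation split unit.
#' @return One-row tibble: `variant`, `acc`, `kappa`, `mf1`, `params_m`,
#'   `f1_W` .. `f1_REM`.
#' @export
run_ablation <- function(variant, bundle = NULL, model_args = list(),
                         train_cfg = train_config(), by = "subject") {
  flags <- variant_flags(variant)
  cfg <- do.call(model_config, utils::modifyList(flags, model_args))
  net <- build_network(cfg, seed = train_cfg$seed)
  row <- tibble::tibble(variant = variant, acc = NA_real_,
                        kappa = NA_real_, mf1 = NA_real_,
                        params_m = round(net$total_parameters / 1e6, 2))
  f1 <- setNames(rep(NA_real_, 5), paste0("f1_", STAGE_LEVELS))
  if (!is.null(bundle)) {
    cv <- cross_validate(bundle, cfg, train_cfg, by = by)
    sm <- summary_metrics(cv$pooled_confusion)
    row$acc <- sm$accuracy
    row$kappa <- sm$kappa
    row$mf1 <- sm$macro_f1
    f1[] <- per_class_metrics(cv$pooled_confusion)$f1
  }
  dplyr::bind_cols(row, tibble::as_tibble(as.list(f1)))
}

#' Sweep the time-axis length or the stem fusion mode
#'
#' Two comparison harnesses: the downsampled time-point count
#' (100/150/200/250/300, i.e. median windows of 30/20/15/12/10 samples) and
#' the multi-scale stem fusion mode (channel concatenation vs branch
#' addition; addition drops the 1x1 fusion convolution). Each sweep point
#' reports its configuration (and parameter count for the fusion axis);
#' training metrics are filled in only when data are supplied.
#'
#' @param axis `"target_t"` or `"msdc_fusion"`.
#' @param values Sweep values; defaults to the standard grid for the axis.
#' @param dataset Optional `lmc_synth_dataset` (target_t axis: re-preprocessed
#'   per sweep point).
#' @param bundle Optional preprocessed bundle (msdc_fusion axis).
#' @param model_args,train_cfg As in [run_ablation()].
#' @param scalogram_args Overrides for [scalogram_config()] (target_t axis).
#' @return Tibble with one row per sweep point.
#' @export
run_sweep <- function(axis = c("target_t", "msdc_fusion"), values = NULL,
                      dataset = NULL, bundle = NULL, model_args = list(),
                      train_cfg = train_config(), scalogram_args = list()) {
  axis <- match.arg(axis)
  if (axis == "target_t") {
    if (is.null(values)) values <- c(100, 150, 200, 250, 300)
    rows <- lapply(values, function(tt) {
      scfg <- do.call(scalogram_config,
                      utils::modifyList(list(target_t = tt), scalogram_args))
      m <- scfg$epoch_seconds * scfg$fs / tt
      row <- tibble::tibble(target_t = tt, window_m = m, acc = NA_real_,
                            kappa = NA_real_, mf1 = NA_real_)
      if (!is.null(dataset)) {
        b <- preprocess_dataset(dataset, scfg)
        cv <- cross_validate(b, do.call(model_config, model_args), train_cfg)
        sm <- summary_metrics(cv$pooled_confusion)
        row$acc <- sm$accuracy
        row$kappa <- sm$kappa
        row$mf1 <- sm$macro_f1
      }
      row
    })
    return(dplyr::bind_rows(rows))
  }
  if (is.null(values)) values <- c("add", "concat")
  if (!all(values %in% c("add", "concat")))
    stop("msdc_fusion values must be 'add' or 'concat'; got ",
         paste(setdiff(values, c("add", "concat")), collapse = ", "))
  rows <- lapply(values, function(fu) {
    cfg <- do.call(model_config,
                   utils::modifyList(list(msdc_fusion = fu), model_args))
    net <- build_network(cfg, seed = train_cfg$seed)
    row <- tibble::tibble(msdc_fusion = fu,
                          params = net$total_parameters,
                          acc = NA_real_, kappa = NA_real_, mf1 = NA_real_)
    if (!is.null(bundle)) {
      cv <- cross_validate(bundle, cfg, train_cfg)
      sm <- summary_metrics(cv$pooled_confusion)
      row$acc <- sm$accuracy
      row$kappa <- sm$kappa
      row$mf1 <- sm$macro_f1
    }
    row
  })
  dplyr::bind_rows(rows)
}

# --- YAML run configuration -------------------------------------------------

cfg_to_plain <- function(cfg) unclass(cfg)

check_known_keys <- function(supplied, constructor, what) {
  known <- names(formals(constructor))
  unknown <- setdiff(names(supplied), known)
  if (length(unknown) > 0)
    stop("unknown ", what, " config key(s): ",
         paste(unknown, collapse = ", "))
}

#' Read / write a unified run configuration
#'
#' A run configuration nests the scalogram, model and training
#' configurations plus a seed and optional file paths, and round-trips
#' losslessly through YAML. Unknown keys are rejected rather than ignored.
#'
#' @param path YAML file path.
#' @param scalogram,model,train Component configurations.
#' @param seed Integer seed.
#' @param paths Optional named list of file paths.
#' @return `read_run_config()` returns a list with elements `scalogram`
#'   (`lmc_scalogram_config`), `model` (`lmc_model_config`), `train`
#'   (`lmc_train_config`), `seed`, `paths`.
#' @export
write_run_config <- function(path, scalogram = scalogram_config(),
                             model = model_config(), train = train_config(),
                             seed = 1, paths = list()) {
  obj <- list(scalogram = cfg_to_plain(scalogram),
              model = cfg_to_plain(model), train = cfg_to_plain(train),
              seed = seed, paths = paths)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  obj <- yaml::read_yaml(path)
  unknown <- setdiff(names(obj), c("scalogram", "model", "train", "seed",
                                   "paths"))
  if (length(unknown) > 0)
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  check_known_keys(obj$scalogram, scalogram_config, "scalogram")
  check_known_keys(obj$model, model_config, "model")
  check_known_keys(obj$train, train_config, "train")
  list(scalogram = do.call(scalogram_config, obj$scalogram %||% list()),
       model = do.call(model_config, obj$model %||% list()),
       train = do.call(train_config, obj$train %||% list()),
       seed = obj$seed %||% 1L, paths = obj$paths %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
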