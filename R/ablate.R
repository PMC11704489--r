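# Ablation grids mirroring the published variant tables:
#  * mutual-inclusion grid: the PC baseline (independent attention paths)
#    versus the full mutually-inclusive block (2 variants);
#  * mix grid: the four primary/auxiliary pairings inside the block;
#  * skip-residue grid: six placements of the skip-residue injection,
#    including the no-modules baseline.

#' Enumerate an ablation grid
#'
#' Returns the variant configurations of one of the three ablation grids,
#' without training anything.
#'
#' @param grid `"mutual_inclusion"` (2 variants), `"mix"` (4) or
#'   `"skip_residue"` (6). The aliases `"table5"`, `"table6"`, `"table7"`
#'   are accepted.
#' @param base a [model_config()] providing every non-varied knob.
#' @return named list of `model_config` objects.
#' @export
ablation_grid <- function(grid = c("mutual_inclusion", "mix", "skip_residue",
                                   "table5", "table6", "table7"),
                          base = tiny_config()) {
  grid <- match.arg(grid)
  grid <- switch(grid, table5 = "mutual_inclusion", table6 = "mix",
                 table7 = "skip_residue", grid)
  modify <- function(...) {
    args <- unclass(base)
    args <- args[setdiff(names(args), "num_conv_stages")]
    over <- list(...)
    args[names(over)] <- over
    do.call(model_config, args)
  }
  switch(grid,
    mutual_inclusion = list(
      pc_net = modify(mutual_inclusion = FALSE),
      mipc_net = modify(mutual_inclusion = TRUE)
    ),
    mix = {
      out <- lapply(mix_variants(), function(v) modify(mix_variant = v))
      names(out) <- mix_variants()
      out
    },
    skip_residue = list(
      none = modify(skip_residue_layers = integer(),
                    da_skip = TRUE, use_encoder_mipc = TRUE),
      sr1 = modify(skip_residue_layers = 1L),
      sr2 = modify(skip_residue_layers = 2L),
      sr3 = modify(skip_residue_layers = 3L),
      sr123 = modify(skip_residue_layers = 1:3),
      baseline = modify(skip_residue_layers = integer(), da_skip = FALSE,
                        use_encoder_mipc = FALSE)
    )
  )
}

#' Run an ablation study
#'
#' Builds and trains every variant of the chosen grid on one shared dataset
#' with one shared seed, then evaluates each on the same images, mirroring
#' the shape of the published ablation tables.
#'
#' @inheritParams ablation_grid
#' @param dataset a `phantom_dataset` shared across variants.
#' @param run a [run_config()] providing optimiser settings and epochs.
#' @param verbose print progress.
#' @return tibble with one row per variant: configuration flags, parameter
#'   count, final training loss, mean DSC and mean HD.
#' @export
run_ablation <- function(grid, dataset, run = run_config(epochs = 5L),
                         base = tiny_config(), verbose = FALSE) {
  cfgs <- ablation_grid(grid, base)
  rows <- lapply(names(cfgs), function(nm) {
    cfg <- cfgs[[nm]]
    model <- build_model(cfg)
    fit <- train_model(model, dataset, run, eval_every = 0L)
    rep <- evaluate_model(model, dataset)
    if (verbose) {
      message(sprintf("%-22s loss %.4f dsc %.4f", nm,
                      fit$history$loss[nrow(fit$history)], rep$mean_dsc))
    }
    tibble::tibble(
      variant = nm,
      mutual_inclusion = cfg$mutual_inclusion,
      mix_variant = cfg$mix_variant,
      da_skip = cfg$da_skip,
      skip_residue = paste(cfg$skip_residue_layers, collapse = "+"),
      encoder_mipc = cfg$use_encoder_mipc,
      n_params = n_parameters(model$layers),
      final_loss = fit$history$loss[nrow(fit$history)],
      mean_dsc = rep$mean_dsc,
      mean_hd = rep$mean_hd
    )
  })
  do.call(rbind, rows)
}
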