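# Multi-seed experiment runner: repeats split + training + evaluation over
# a set of seeds and reports per-seed metrics with mean and standard
# deviation, the convention for stochastic DTA benchmarks.

#' Repeat a training study over several seeds
#'
#' For each seed: split the records, train the full two-branch model, and
#' evaluate on the held-out test set.
#'
#' @param data a `dta_dataset`.
#' @param seeds integer vector of seeds (five by convention).
#' @param encoder_cfg an [encoder_config()].
#' @param gin_cfg a [gin_config()].
#' @param train_cfg a [train_config()]; its seed is replaced per run.
#' @param scheme split scheme (see [split_spec()]).
#' @param fractions train/val/test fractions.
#' @return data frame of per-seed test metrics with a `summary` attribute
#'   (mean and sd per metric).
#' @export
run_seed_replicates <- function(data, seeds = 1:5,
                                encoder_cfg = encoder_config(),
                                gin_cfg = gin_config(),
                                train_cfg = train_config(),
                                scheme = "random",
                                fractions = c(0.8, 0.1, 0.1)) {
  md <- prepare_model_data(data, encoder_cfg)
  rows <- lapply(seeds, function(s) {
    sp <- make_split(md$records, split_spec(scheme, fractions, seed = s))
    tc <- train_cfg
    tc$seed <- as.integer(s)
    model <- joint_train(md, sp$train, sp$val, gin_cfg, tc)
    preds <- predict_affinity(model, md, sp$test)
    m <- basic_metrics(md$records$affinity[sp$test], preds$final_pred)
    data.frame(seed = s, mse = m$mse, ci = m$ci, rm2 = m$rm2,
               pearson = m$pearson, spearman = m$spearman, n = m$n)
  })
  out <- do.call(rbind, rows)
  metr <- c("mse", "ci", "rm2", "pearson", "spearman")
  attr(out, "summary") <- data.frame(
    metric = metr,
    mean = vapply(metr, function(k) mean(out[[k]]), numeric(1)),
    sd = vapply(metr, function(k) stats::sd(out[[k]]), numeric(1)))
  out
}
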