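#' Transfer a trained CNN encoder to a new input width
#'
#' Copies the convolutional kernel weights exactly (3x3 kernels are
#' width-agnostic) and rebuilds the flatten/dense head, freshly initialized,
#' for the target input width. The optimizer caches of the copied layers are
#' reset.
#'
#' @param source A trained `grn_cnn` model.
#' @param target_input_width Number of input features for the target species
#'   (`2S`, even).
#' @param seed Seed for the re-initialized head (default: derived from the
#'   source config seed).
#' @return An untrained-head `grn_cnn` for the target width, convolutional
#'   weights identical to the source.
#' @export
transfer_encoder <- function(source, target_input_width,
                             seed = derive_seed(source$config$seed, "transfer")) {
  if (!inherits(source, "grn_cnn")) {
    fail("transfer needs a CNN source model, got %s", class(source)[1])
  }
  cfg <- source$config
  cfg$seed <- as.integer(seed)
  target <- build_model(cfg, target_input_width)
  for (i in seq_along(target$layers)) {
    if (target$layers[[i]]$type == "conv") {
      src <- source$layers[[i]]
      stopifnot(identical(dim(src$W), dim(target$layers[[i]]$W)))
      target$layers[[i]]$W <- src$W
      target$layers[[i]]$b <- src$b
    }
  }
  target
}

#' Plan for a cross-species transfer experiment
#'
#' @param target_train_size Pairs per class drawn for target-species training
#'   (default 100).
#' @param target_test_size Pairs per class in the fixed target test set
#'   (default 500).
#' @param config [model_config()] used for source and target CNN training.
#' @param epochs Target-training epochs (default: config value).
#' @param source_model Optional pre-trained source `grn_cnn`; if `NULL` the
#'   source model is trained from the source data inside the experiment.
#' @param seed Integer seed for the pair draws.
#' @return A list of class `transfer_plan`.
#' @export
transfer_plan <- function(target_train_size = 100L, target_test_size = 500L,
                          config = model_config("cnn"), epochs = config$epochs,
                          source_model = NULL, seed = 1L) {
  if (target_train_size <= 0 || target_test_size <= 0) fail("sizes must be positive")
  structure(list(target_train_size = as.integer(target_train_size),
                 target_test_size = as.integer(target_test_size),
                 config = config, epochs = as.integer(epochs),
                 source_model = source_model, seed = as.integer(seed)),
            class = "transfer_plan")
}

#' Run the three-mode cross-species transfer experiment
#'
#' Draws a target-species training sample (`target_train_size` pairs per
#' class) and a disjoint fixed test set (`target_test_size` per class), then
#' trains and evaluates three CNNs sharing that test set:
#' \describe{
#'   \item{scratch}{random initialization, trained on the small target set
#'     only (the no-transfer baseline);}
#'   \item{frozen}{convolutional weights copied from the source model and
#'     frozen; only the dense head trains;}
#'   \item{fine_tune}{convolutional weights copied and the whole network
#'     trained further.}
#' }
#'
#' @param plan A [transfer_plan()].
#' @param source_data List with `x` (pair feature matrix) and `y` (0/1
#'   labels) for the source species; used to train the source model when the
#'   plan does not carry one.
#' @param target_data List with `x` and `y` for the target species; must
#'   contain at least `target_train_size + target_test_size` pairs per class.
#' @return A data frame `(mode, f1, auc, seed)` of class
#'   `transfer_result`. An F1 undefined at threshold 0.5 (no predicted
#'   positives) is reported as 0.
#' @export
run_transfer_experiment <- function(plan, source_data, target_data) {
  stopifnot(inherits(plan, "transfer_plan"))
  y <- target_data$y
  need <- plan$target_train_size + plan$target_test_size
  if (min(sum(y == 1), sum(y == 0)) < need) {
    fail("target data has %d/%d pairs per class but %d are needed",
         sum(y == 1), sum(y == 0), need)
  }
  draw <- with_seed(derive_seed(plan$seed, "target_draw"), {
    pick <- function(cls) {
      ix <- sample(which(y == cls))
      list(train = ix[seq_len(plan$target_train_size)],
           test = ix[plan$target_train_size + seq_len(plan$target_test_size)])
    }
    list(pos = pick(1), neg = pick(0))
  })
  tr_ix <- c(draw$pos$train, draw$neg$train)
  te_ix <- c(draw$pos$test, draw$neg$test)
  Xtr <- target_data$x[tr_ix, , drop = FALSE]
  ytr <- y[tr_ix]
  Xte <- target_data$x[te_ix, , drop = FALSE]
  yte <- y[te_ix]

  source_model <- plan$source_model
  if (is.null(source_model)) {
    cfg <- plan$config
    cfg$seed <- derive_seed(plan$seed, "source_model")
    source_model <- build_model(cfg, ncol(source_data$x))
    source_model <- train_model(source_model, source_data$x, source_data$y)
  }

  eval_mode <- function(model) {
    p <- predict(model, Xte)
    f1 <- suppressWarnings(confusion_metrics(p, yte)$f1)
    data.frame(f1 = ifelse(is.na(f1), 0, f1), auc = roc_auc(p, yte)$auc)
  }
  width <- ncol(Xtr)
  res <- list()
  # scratch: same architecture, random init, no source weights involved
  cfg_s <- plan$config
  cfg_s$seed <- derive_seed(plan$seed, "scratch")
  m_scratch <- build_model(cfg_s, width)
  m_scratch <- train_model(m_scratch, Xtr, ytr, epochs = plan$epochs)
  res$scratch <- eval_mode(m_scratch)
  # frozen: transferred conv weights, frozen through training
  m_frozen <- transfer_encoder(source_model, width,
                               seed = derive_seed(plan$seed, "frozen_head"))
  m_frozen <- train_model(m_frozen, Xtr, ytr, epochs = plan$epochs,
                          freeze_conv = TRUE)
  res$frozen <- eval_mode(m_frozen)
  # fine_tune: transferred conv weights, everything trainable
  m_ft <- transfer_encoder(source_model, width,
                           seed = derive_seed(plan$seed, "finetune_head"))
  m_ft <- train_model(m_ft, Xtr, ytr, epochs = plan$epochs)
  res$fine_tune <- eval_mode(m_ft)

  out <- do.call(rbind, lapply(names(res), function(m) {
    cbind(data.frame(mode = m, stringsAsFactors = FALSE), res[[m]],
          data.frame(seed = plan$seed))
  }))
  class(out) <- c("transfer_result", "data.frame")
  out
}
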