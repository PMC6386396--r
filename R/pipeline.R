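# End-to-end orchestration: configuration profiles, the corpus ->
# cochleogram -> model -> analyses pipeline, control-experiment variants,
# and plain-text model serialization with a hashed artifact manifest.

#' Build a run configuration
#'
#' Two profiles: `"test"` (desk scale: 12-phoneme inventory, 96 tokens,
#' 96 cochlear channels, 6-layer network with 16/24/32 maps, 2000 patches
#' per layer) and `"full"` (study scale: 33 phonemes, 194 channels,
#' 12-layer network with 100..500 maps). Any field can be overridden via
#' `...`.
#'
#' @param profile `"test"` or `"full"`.
#' @param seed master seed; corpus/training/analysis seeds derive from it.
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @param ... field overrides.
#' @return a `"run_config"` list.
#' @export
run_config <- function(profile = c("test", "full"), seed = 1L,
                       out_dir = tempfile("shmax_run_"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "test") {
    list(n_phonemes = 12L, n_tokens = 96L, jitter_sd = 0.05,
         n_channels = 96L, f_lo = 73, f_hi = 7630, fs = 16000L,
         n_maps = c(16L, 24L, 32L), kernels = 10L, strides = c(2L, 2L, 1L),
         lambda = 1, pool_mode = "max", regularizer = "L1",
         n_patches = 2000L, epochs = 3L, folds = 20L, n_groups = 6L,
         analyses = c("psi", "decode", "tvi"))
  } else {
    list(n_phonemes = 33L, n_tokens = 600L, jitter_sd = 0.05,
         n_channels = 194L, f_lo = 73, f_hi = 7630, fs = 16000L,
         n_maps = c(100L, 200L, 300L, 400L, 500L, 500L), kernels = 10L,
         strides = c(2L, 2L, 1L, 1L, 1L, 1L),
         lambda = 1, pool_mode = "max", regularizer = "L1",
         n_patches = 50000L, epochs = 3L, folds = 20L, n_groups = 6L,
         analyses = c("psi", "decode", "tvi"))
  }
  cfg <- utils::modifyList(base, list(...))
  cfg$profile <- profile
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  structure(cfg, class = "run_config")
}

config_arch <- function(cfg) {
  shmax_architecture(n_maps = cfg$n_maps, kernels = cfg$kernels,
                     strides = cfg$strides, lambda = cfg$lambda,
                     pool_mode = cfg$pool_mode, regularizer = cfg$regularizer)
}

#' Run the full pipeline
#'
#' Synthesizes the corpus, computes the cochleogram, trains the network,
#' and runs the toggled analyses (per-layer selectivity + F-ratio, acoustic
#' parameter decoding at the top layer, TVI correlations). All artifacts are
#' written under `config$out_dir` together with a `manifest.tsv` of MD5
#' content hashes; reruns with an identical configuration write identical
#' hashes.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return (invisibly) list with `config`, `corpus`, `model`, `selectivity`,
#'   `decoding`, `tvi`, `paths`, `manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[synth] %d tokens over %d phonemes", cfg$n_tokens, cfg$n_phonemes)
  inv <- make_inventory(cfg$n_phonemes, seed = cfg$seed)
  corpus <- synthesize(inv, cfg$n_tokens, jitter_sd = cfg$jitter_sd,
                       seed = cfg$seed + 1L, fs = cfg$fs)
  paths <- as.list(write_corpus(corpus, cfg$out_dir))

  say("[cochlea] %d channels", cfg$n_channels)
  fb <- build_filterbank(cfg$n_channels, cfg$f_lo, cfg$f_hi, cfg$fs)
  coch <- cochleogram(corpus$wave, fb)

  say("[train] %s", paste(cfg$n_maps, collapse = "/"))
  arch <- config_arch(cfg)
  model <- train_network(list(coch), arch, n_patches = cfg$n_patches,
                         seed = cfg$seed + 2L, epochs = cfg$epochs,
                         verbose = verbose)
  paths$model <- write_model(model, file.path(cfg$out_dir, "model"))

  geo <- model$geometry
  results <- list(config = cfg, corpus = corpus, model = model)

  if ("psi" %in% cfg$analyses) {
    say("[psi] per-layer selectivity")
    analysis_layers <- analysis_layer_names(arch)
    sel <- lapply(analysis_layers, function(nm) {
      gi <- match(nm, geo$layer)
      layer_selectivity(model$activations[[nm]][[1]], corpus$transcript,
                        rf = geo$rf[gi], jump = geo$jump[gi], fs = cfg$fs,
                        n_groups = cfg$n_groups, seed = cfg$seed + 3L)
    })
    names(sel) <- analysis_layers
    results$selectivity <- sel
    frat <- data.frame(layer = analysis_layers,
                       f_ratio = vapply(sel, `[[`, 0, "f_ratio"),
                       sparseness = vapply(sel, `[[`, 0, "sparseness"),
                       n_active = vapply(sel, function(s) length(s$active), 0L))
    paths$f_ratio <- file.path(cfg$out_dir, "f_ratio.tsv")
    write.table(frat, paths$f_ratio, sep = "\t", row.names = FALSE, quote = FALSE)
    top <- sel[[length(sel)]]
    if (!is.null(top$psi)) {
      paths$psi <- file.path(cfg$out_dir, "psi_top_layer.tsv")
      write.table(cbind(unit = rownames(top$psi), as.data.frame(unclass(top$psi))),
                  paths$psi, sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if ("decode" %in% cfg$analyses && !is.null(results$selectivity)) {
    say("[decode] acoustic parameters at the top layer")
    top_layer <- tail(analysis_layer_names(arch), 1L)
    top <- results$selectivity[[top_layer]]
    params <- estimate_params(coch, corpus$transcript, corpus)
    if (length(top$active) >= 2L) {
      X <- amplitude_matrix(top$table, top$active)
      dec <- lapply(c("f0", "f1", "f2", "vot", "spectral_peak"), function(p) {
        y <- params[[p]]
        if (sum(!is.na(y)) < cfg$folds) return(NULL)
        res <- decode_param(X, y, folds = cfg$folds, seed = cfg$seed + 4L,
                            param_name = p)
        data.frame(param = p, mean_accuracy = mean(res$linear$accuracy),
                   mean_random = mean(res$random), p_value = res$p_value,
                   n_instances = res$linear$n)
      })
      dec <- do.call(rbind, dec)
      results$decoding <- dec
      paths$decoding <- file.path(cfg$out_dir, "decoding.tsv")
      write.table(dec, paths$decoding, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    results$params <- params
  }

  if ("tvi" %in% cfg$analyses && !is.null(results$selectivity)) {
    say("[tvi] formant-dynamics correlations")
    top_layer <- tail(analysis_layer_names(arch), 1L)
    top <- results$selectivity[[top_layer]]
    contours <- build_contours(corpus$frame_truth, corpus$transcript, fs = cfg$fs)
    mresp <- mean_phoneme_responses(top$table, top$active)
    tv <- data.frame(
      unit = top$active,
      f1 = tvi_correlation(mresp, tvi(contours, "f1"))$correlation,
      f2 = tvi_correlation(mresp, tvi(contours, "f2"))$correlation)
    results$tvi <- tv
    paths$tvi <- file.path(cfg$out_dir, "tvi_correlations.tsv")
    write.table(tv, paths$tvi, sep = "\t", row.names = FALSE, quote = FALSE)
  }

  files <- unlist(paths, use.names = FALSE)
  files <- files[file.exists(files) & !dir.exists(files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mpath <- file.path(cfg$out_dir, "manifest.tsv")
  write.table(manifest[order(manifest$file), ], mpath, sep = "\t",
              row.names = FALSE, quote = FALSE)
  results$paths <- paths
  results$manifest <- manifest
  invisible(results)
}

# analysis layers: every C layer (or the S layer when its C pass-through)
analysis_layer_names <- function(arch) {
  nms <- names(arch)
  out <- character(0)
  for (i in seq_along(nms)) {
    l <- arch[[i]]
    if (l$kind == "C") {
      out <- c(out, if (l$pool_mode != "none") nms[i] else nms[i - 1L])
    }
  }
  out
}

#' Control-experiment variant suite
#'
#' Trains the pooling variants (max, average, none) and the L2-regularizer
#' control on the same corpus and seed, plus a wide-kernel variant of the
#' final S layer (kernel doubled, preceding layers reused) whose receptive
#' field matches a one-layer-deeper stack. Reports top-layer F-ratio, mean
#' lifetime sparseness, and active-unit counts per variant, with a content
#' hash of each trained model.
#'
#' @param cochleograms training corpus (list of cochleograms).
#' @param transcript corpus transcript.
#' @param base_arch the base (max-pooling, L1) architecture.
#' @param n_patches,seed,epochs training controls.
#' @param n_groups,fs analysis controls.
#' @param variants subset of
#'   `c("max", "average", "none", "L2")` to run.
#' @return data frame: `variant`, `analysis_layer`, `f_ratio`, `sparseness`,
#'   `n_active`, `model_hash`.
#' @export
variant_suite <- function(cochleograms, transcript, base_arch,
                          n_patches = 2000L, seed = 1L, epochs = 3L,
                          n_groups = 6L, fs = 16000L,
                          variants = c("max", "average", "none", "L2")) {
  make_variant <- function(v) {
    arch <- base_arch
    for (nm in names(arch)) {
      if (v %in% c("max", "average", "none") && arch[[nm]]$kind == "C") {
        arch[[nm]]$pool_mode <- v
      }
      if (v == "L2" && arch[[nm]]$kind == "S") arch[[nm]]$regularizer <- "L2"
    }
    arch
  }
  rows <- lapply(variants, function(v) {
    arch <- make_variant(v)
    model <- train_network(cochleograms, arch, n_patches = n_patches,
                           seed = seed, epochs = epochs)
    nm <- tail(analysis_layer_names(arch), 1L)
    geo <- model$geometry
    gi <- match(nm, geo$layer)
    sel <- layer_selectivity(model$activations[[nm]][[1]], transcript,
                             rf = geo$rf[gi], jump = geo$jump[gi], fs = fs,
                             n_groups = n_groups, seed = seed)
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    write_bank_tsv(model$banks[[length(model$banks)]], tmp)
    data.frame(variant = v, analysis_layer = nm, f_ratio = sel$f_ratio,
               sparseness = sel$sparseness, n_active = length(sel$active),
               model_hash = unname(tools::md5sum(tmp)))
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# plain-text model serialization

write_bank_tsv <- function(bank, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kernel\t%d\n# u\t%d\n# lambda\t%.17g\n# regularizer\t%s",
                     bank$kernel, bank$u, bank$lambda, bank$regularizer), con)
  write.table(format(bank$B, digits = 17), con, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_bank_tsv <- function(path) {
  hdr <- readLines(path, n = 4L)
  get <- function(i) strsplit(hdr[i], "\t")[[1]][2]
  B <- as.matrix(read.table(path, skip = 4L, sep = "\t"))
  dimnames(B) <- NULL
  new_bank(B, kernel = as.integer(get(1)), u = as.integer(get(2)),
           lambda = as.numeric(get(3)), regularizer = get(4), trace = numeric(0))
}

#' Serialize / load a trained model (plain-text container)
#'
#' Writes the architecture table (`arch.tsv`) and one TSV per dictionary
#' bank under `dir`. Activations are not serialized.
#'
#' @param model a trained model.
#' @param dir target directory.
#' @return `dir` (write) / a `"shmax_model"` without activations (read).
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arch_df <- do.call(rbind, lapply(names(model$arch), function(nm) {
    l <- model$arch[[nm]]
    data.frame(layer = nm, kind = l$kind, kernel = l$kernel,
               n_maps = l$n_maps %||% NA_integer_, conv_stride = l$conv_stride,
               pool_size = l$pool_size, pool_stride = l$pool_stride,
               pool_mode = l$pool_mode, lambda = l$lambda,
               regularizer = l$regularizer)
  }))
  write.table(arch_df, file.path(dir, "arch.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (nm in names(model$banks)) {
    write_bank_tsv(model$banks[[nm]], file.path(dir, paste0("bank_", nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  arch_df <- read.table(file.path(dir, "arch.tsv"), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  layers <- list()
  for (i in seq_len(nrow(arch_df))) {
    r <- arch_df[i, ]
    layers[[r$layer]] <- layer_spec(
      kind = r$kind, kernel = r$kernel,
      n_maps = if (r$kind == "S") r$n_maps else NULL,
      conv_stride = r$conv_stride, pool_size = r$pool_size,
      pool_stride = r$pool_stride, pool_mode = r$pool_mode,
      lambda = r$lambda, regularizer = r$regularizer)
  }
  arch <- structure(layers, class = "shmax_arch")
  banks <- list()
  for (nm in names(arch)) {
    p <- file.path(dir, paste0("bank_", nm, ".tsv"))
    if (file.exists(p)) banks[[nm]] <- read_bank_tsv(p)
  }
  structure(list(arch = arch, banks = banks, activations = NULL,
                 geometry = layer_geometry(arch)),
            class = "shmax_model")
}
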