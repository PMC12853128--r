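# End-to-end orchestration: annotate -> featurize -> train x3 -> ensemble
# -> evaluate, driven by a single YAML configuration, with a manifest
# recording seeds and output checksums for reproducibility.

PIPELINE_KEYS <- c("inputs", "lexicon", "cutoff", "min_binding", "seed",
                   "epochs", "lr", "batch_size", "out_dir", "sasa_points")

#' Read and validate a pipeline configuration
#'
#' YAML with keys: `inputs` (list of records with `structure`, `fasta`,
#' `prott5`, `esm2` paths), optional `lexicon`, `cutoff` (default 3.5),
#' `min_binding` (default 5), `seed`, `epochs`, `lr`, `batch_size`,
#' `sasa_points`, and `out_dir`.  Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "glycobind_config_error")
  }
  if (is.null(cfg$inputs) || !length(cfg$inputs)) {
    abort("config must list at least one input record", class = "glycobind_config_error")
  }
  cfg$cutoff <- cfg$cutoff %||% 3.5
  cfg$min_binding <- cfg$min_binding %||% 5
  cfg$seed <- cfg$seed %||% 1
  cfg$out_dir <- cfg$out_dir %||% "glycobind_run"
  cfg$sasa_points <- cfg$sasa_points %||% 960
  for (inp in cfg$inputs) {
    for (k in c("structure", "fasta", "prott5", "esm2")) {
      if (is.null(inp[[k]])) {
        abort(sprintf("input record missing '%s'", k), class = "glycobind_config_error")
      }
      if (!file.exists(inp[[k]])) {
        abort(sprintf("input file not found: %s", inp[[k]]), class = "glycobind_data_error")
      }
    }
  }
  cfg
}

# masked full sequence: '-' at unmodeled (gap) positions
masked_sequence <- function(chain) {
  ch <- strsplit(chain$full_sequence, "")[[1]]
  ch[chain$labels == "gap"] <- "-"
  paste(ch, collapse = "")
}

#' Turn an annotated chain plus features into training samples
#'
#' One sample per modeled, non-gap full-sequence position: the 31-wide
#' window encoding over the gap-masked full sequence, the 2340-wide feature
#' vector, and the 0/1 label.
#'
#' @param chain Annotated [chain_record].
#' @param structural Modeled-residue structural matrix (L_modeled x 36).
#' @param prott5,esm2 Embedding matrices over modeled residues.
#' @return A [labeled_set()].
#' @export
chain_to_samples <- function(chain, structural, prott5, esm2) {
  feats <- assemble_fnn_input(prott5, structural, esm2)
  keep <- which(chain$labels != "gap")
  seqm <- masked_sequence(chain)
  windows <- t(vapply(keep, function(p) window_encode(seqm, p), integer(31)))
  modeled_idx <- chain$alignment[keep]
  labeled_set(windows, feats[modeled_idx, , drop = FALSE],
              as.numeric(chain$labels[keep] == "positive"))
}

concat_sets <- function(sets) {
  labeled_set(do.call(rbind, lapply(sets, `[[`, "windows")),
              do.call(rbind, lapply(sets, `[[`, "features")),
              unlist(lapply(sets, `[[`, "labels")))
}

#' Run the full pipeline from a configuration
#'
#' Stages: structure annotation, structural featurization, embedding
#' ingestion, training of the three imbalance-strategy models, the 2:1:1
#' ensemble, and evaluation; each stage's outputs land under `out_dir` and
#' a `manifest.json` records the configuration, seeds and MD5 checksums of
#' every artifact.
#'
#' @param config Path to a YAML config or a validated config list.
#' @param epochs Optional epoch override (useful for smoke runs).
#' @param verbose Log stage progress?
#' @return Invisibly, a list with `metrics` ([evaluate_predictions()]
#'   report), `ensemble`, `manifest_path`.
#' @export
run_pipeline <- function(config, epochs = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "glycobind_stage_error")
    })
    say("stage %-12s done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  lexicon <- stage("lexicon", read_carb_lexicon(cfg$lexicon))

  chains <- stage("annotate", {
    out <- list()
    for (inp in cfg$inputs) {
      st <- parse_structure(inp$structure)
      carb <- collect_carb_atoms(st, lexicon)
      fa <- read_fasta_seqs(inp$fasta)
      for (ch in st$chains) {
        full <- if (length(fa) == 1) fa else fa[[ch$chain_id]]
        ch <- attach_full_sequence(ch, full)
        ch <- annotate_binding(ch, carb, cutoff = cfg$cutoff)
        dec <- chain_filters(ch, min_binding = cfg$min_binding)
        if (!dec$keep) {
          say("  chain %s dropped: %s", ch$chain_id, dec$reason)
          next
        }
        out[[length(out) + 1]] <- list(chain = ch, inp = inp)
      }
    }
    if (!length(out)) abort("no chain passed the filters", class = "glycobind_data_error")
    out
  })
  ann_path <- file.path(cfg$out_dir, "annotation.cpb.tsv")
  write_annotation(lapply(chains, `[[`, "chain"), ann_path)

  sets <- stage("featurize", lapply(chains, function(rec) {
    ch <- rec$chain
    L <- nrow(ch$modeled)
    structural <- assemble_structural(ch, n_points = cfg$sasa_points)
    prott5 <- read_embedding(rec$inp$prott5, expected_length = L, expected_width = 1024)
    esm2 <- read_embedding(rec$inp$esm2, expected_length = L, expected_width = 1280)
    chain_to_samples(ch, structural, prott5, esm2)
  }))
  full_set <- concat_sets(sets)

  net_cfg <- net_config_desk()
  if (!is.null(cfg$lr)) net_cfg$lr <- cfg$lr
  if (!is.null(cfg$batch_size)) net_cfg$batch_size <- cfg$batch_size
  epochs <- epochs %||% cfg$epochs
  ens <- stage("train", build_ensemble(full_set, net_cfg,
                                       seeds = cfg$seed + 0:2, epochs = epochs,
                                       verbose = FALSE))
  model_path <- file.path(cfg$out_dir, "ensemble.rds")
  save_model(ens, model_path)

  prob <- stage("predict", predict(ens, full_set$windows, full_set$features))
  pred_path <- file.path(cfg$out_dir, "predictions.tsv")
  write.table(tibble(probability = prob, label = full_set$labels), pred_path,
              sep = "\t", row.names = FALSE, quote = FALSE)

  metrics <- stage("evaluate", evaluate_predictions(prob, full_set$labels))
  metrics_path <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(unclass(metrics), metrics_path, auto_unbox = TRUE, digits = NA)

  text_outputs <- c(ann_path, pred_path, metrics_path)
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    seeds = cfg$seed + 0:2,
    n_samples = length(full_set$labels),
    outputs = as.list(tools::md5sum(text_outputs)))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, ensemble = ens, manifest_path = manifest_path))
}
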