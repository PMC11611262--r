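# End-to-end orchestration: synth/load -> extract -> encode -> embed ->
# SFS -> GA -> train -> eval. Every stage writes a plain TSV/JSON artifact
# so any stage can be inspected or replaced.

#' Pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param flank residues each side of the site (fragment length `2*flank+1`).
#' @param prot_sim,frag_sim identity thresholds of the two redundancy passes
#'   (`NA` skips a pass).
#' @param train_fraction training fraction of the balanced dataset.
#' @param encoder an [encoder_config()].
#' @param embedding an [embedding_config()].
#' @param prefilter_n columns kept from each high-dimensional block (EAAC,
#'   BINARY) by gradient-boosting importance.
#' @param sfs_max cap on SFS steps (NULL: full curve).
#' @param sfs_min_keep lower bound on features kept per SFS pass, so the
#'   combined matrix stays wide enough for the genetic algorithm.
#' @param ga a [ga_config()].
#' @param skip_ga train directly on the combined SFS features.
#' @param species free-text tag recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, flank = 20L, prot_sim = 0.3,
                            frag_sim = 0.4, train_fraction = 0.8,
                            encoder = encoder_config(),
                            embedding = embedding_config(),
                            prefilter_n = 250L, sfs_max = NULL,
                            sfs_min_keep = 50L, ga = ga_config(),
                            skip_ga = FALSE, species = "synthetic") {
  structure(list(seed = as.integer(seed), flank = as.integer(flank),
                 prot_sim = prot_sim, frag_sim = frag_sim,
                 train_fraction = train_fraction, encoder = encoder,
                 embedding = embedding, prefilter_n = as.integer(prefilter_n),
                 sfs_max = sfs_max, sfs_min_keep = as.integer(sfs_min_keep),
                 ga = ga, skip_ga = isTRUE(skip_ga), species = species),
            class = "pipeline_config")
}

# Build the full (physchem + embedding) feature matrix for a fragment set.
.full_feature_block <- function(fragments, encoder, embed_model) {
  blocks <- encode_physchem(fragments, encoder)
  blocks$EMBED <- encode_fragment_embedding(fragments, embed_model)
  combine_blocks(blocks)
}

#' Run the full prediction pipeline
#'
#' Stages, in order: load or synthesize proteins and site annotations;
#' protein redundancy reduction; fragment extraction; fragment redundancy
#' reduction; negative down-sampling to a balanced set; stratified 80/20
#' split; physicochemical encoding with gradient-boosting pre-filtering of
#' the EAAC and BINARY blocks; embedding training (on training fragments
#' only) and encoding; sequential forward selection per feature family;
#' offspring-competition GA on the combined selected features; final SVM
#' training and held-out evaluation.
#'
#' @param config a [pipeline_config()].
#' @param proteins named character vector of sequences (or NULL to use
#'   `synth`).
#' @param sites site annotation data.frame (see [read_sites()]).
#' @param synth arguments passed to [generate_proteins()] when `proteins` is
#'   NULL.
#' @param out_dir directory for stage artifacts (NULL: nothing written).
#' @param verbose print stage progress.
#' @return object of class `phospho_model`: the trained classifier, selected
#'   feature names, embedding model, encoder config, the held-out
#'   [eval_report()] and all intermediate results.
#' @export
run_pipeline <- function(config = pipeline_config(), proteins = NULL,
                         sites = NULL, synth = list(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[phosphoseed] ", ...)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(fn, ...) if (!is.null(out_dir)) fn(...) else invisible(NULL)

  # --- stage: data ----------------------------------------------------------
  if (is.null(proteins)) {
    say("synthesizing proteins")
    args <- utils::modifyList(list(n = 220L, seed = config$seed), synth)
    gen <- do.call(generate_proteins, args)
    proteins <- gen$proteins
    sites <- gen$sites
  }
  stopifnot(!is.null(sites))

  # --- stage: protein redundancy -------------------------------------------
  if (!is.na(config$prot_sim)) {
    keep <- reduce_redundancy(unname(proteins), config$prot_sim)
    say("protein redundancy: ", length(keep), "/", length(proteins), " kept")
    proteins <- proteins[keep]
    sites <- sites[sites$protein_id %in% names(proteins), , drop = FALSE]
  }

  # --- stage: fragments -----------------------------------------------------
  frags <- extract_fragments(proteins, sites, config$flank)
  if (!is.na(config$frag_sim)) {
    keep <- reduce_redundancy(frags$sequence, config$frag_sim)
    say("fragment redundancy: ", length(keep), "/", nrow(frags), " kept")
    frags <- frags[keep, , drop = FALSE]
  }

  # --- stage: balance + split ----------------------------------------------
  balanced <- build_balanced_dataset(frags[frags$label == "positive", ],
                                     frags[frags$label == "negative", ],
                                     seed = config$seed)
  split <- split_train_test(balanced, config$train_fraction,
                            seed = config$seed + 1L)
  dataset <- rbind(split$train, split$test)
  is_train <- rep(c(TRUE, FALSE), c(nrow(split$train), nrow(split$test)))
  y <- as.integer(dataset$label == "positive")
  say("balanced dataset: ", nrow(dataset), " fragments (",
      sum(is_train), " train)")
  emit(utils::write.table, cbind(dataset, train = is_train),
       file.path(out_dir, "fragments.tsv"), sep = "\t", quote = FALSE,
       row.names = FALSE)

  # --- stage: physicochemical features -------------------------------------
  say("encoding physicochemical blocks")
  blocks <- encode_physchem(dataset$sequence, config$encoder)
  for (bn in intersect(c("EAAC", "BINARY"), names(blocks))) {
    rk <- gbt_importance(blocks[[bn]]$values[is_train, , drop = FALSE],
                         y[is_train], seed = config$seed)
    blocks[[bn]] <- prefilter_top(blocks[[bn]], rk, config$prefilter_n)
  }
  physchem <- combine_blocks(blocks, "PHYSCHEM")
  say("physchem block: ", ncol(physchem$values), " features")

  sfs_pass <- function(block, tag) {
    rk <- gbt_importance(block$values[is_train, , drop = FALSE], y[is_train],
                         seed = config$seed)
    res <- sfs(block$values[is_train, , drop = FALSE], y[is_train], rk,
               max_features = config$sfs_max, seed = config$seed)
    keep_n <- max(length(res$best_subset),
                  min(config$sfs_min_keep, ncol(block$values)))
    keep <- sort(rk$order[seq_len(keep_n)])
    say(tag, " SFS: best prefix ", length(res$best_subset), ", keeping ",
        keep_n, " (AUC ", round(res$best_auc, 4), ")")
    emit(write_sfs_tsv, res, file.path(out_dir, paste0("sfs_", tag, ".tsv")))
    feature_block(block$block_name, block$feature_names[keep],
                  block$values[, keep, drop = FALSE])
  }
  physchem_sel <- sfs_pass(physchem, "physchem")

  # --- stage: embedding -----------------------------------------------------
  say("training k-mer embedding (k=", config$embedding$k, ", w=",
      config$embedding$w, ")")
  embed_cfg <- config$embedding
  embed_cfg$seed <- config$seed
  embed_model <- train_embedding(
    kmer_corpus(dataset$sequence[is_train], embed_cfg$k), embed_cfg)
  embed <- encode_fragment_embedding(dataset$sequence, embed_model)
  embed_sel <- sfs_pass(embed, "embedding")

  # --- stage: GA ------------------------------------------------------------
  combined <- combine_blocks(list(physchem_sel, embed_sel), "COMBINED")
  say("combined selected features: ", ncol(combined$values))
  ga_cfg <- config$ga
  ga_cfg$seed <- config$seed
  if (!config$skip_ga) {
    if (ncol(combined$values) < ga_cfg$chromosome_size) {
      warning("combined width ", ncol(combined$values),
              " < chromosome size; shrinking chromosome")
      ga_cfg$chromosome_size <- ncol(combined$values)
    }
    ga_res <- evolve(combined$values[is_train, , drop = FALSE], y[is_train],
                     ga_cfg, verbose = verbose)
    sel_names <- combined$feature_names[ga_res$best$genes]
    emit(utils::write.table, ga_res$history,
         file.path(out_dir, "ga_history.tsv"), sep = "\t", quote = FALSE,
         row.names = FALSE)
  } else {
    ga_res <- NULL
    sel_names <- combined$feature_names
  }
  emit(jsonlite::write_json, sel_names, file.path(out_dir, "subset.json"))

  # --- stage: final model + evaluation -------------------------------------
  say("training final classifier on ", length(sel_names), " features")
  Xtr <- combined$values[is_train, sel_names, drop = FALSE]
  Xte <- combined$values[!is_train, sel_names, drop = FALSE]
  model <- train_classifier(Xtr, y[is_train], seed = config$seed)
  scores <- predict(model, Xte)
  report <- eval_report(scores, y[!is_train])
  say(sprintf("held-out: ACC %.4f SN %.4f SP %.4f MCC %.4f AUC %.4f",
              report$acc, report$sn, report$sp, report$mcc, report$auc))
  emit(jsonlite::write_json,
       report[c("acc", "sn", "sp", "mcc", "auc", "sn_sp_gap", "threshold")],
       file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
  emit(utils::write.table, report$roc, file.path(out_dir, "roc.tsv"),
       sep = "\t", quote = FALSE, row.names = FALSE)

  result <- structure(list(
    config = config, classifier = model, selected_features = sel_names,
    embedding = embed_model, ga = ga_res, report = report,
    dataset = dataset, is_train = is_train,
    physchem_features = physchem_sel$feature_names,
    embed_features = embed_sel$feature_names), class = "phospho_model")

  if (!is.null(out_dir)) {
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(.serialize_config(config), cfg_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     package_version = as.character(
                       utils::packageVersion("phosphoseed")),
                     n_fragments = nrow(dataset),
                     n_selected = length(sel_names))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

.serialize_config <- function(config) {
  if (is.list(config)) lapply(unclass(config), .serialize_config) else config
}

#' @export
print.phospho_model <- function(x, ...) {
  cat("<phospho_model: ", length(x$selected_features), " features, held-out ",
      sep = "")
  cat(sprintf("ACC %.4f AUC %.4f>\n", x$report$acc, x$report$auc))
  invisible(x)
}

#' Score new candidate sites with a trained pipeline model
#'
#' Extracts fragments for the given sites, rebuilds the model's feature
#' representation (physicochemical blocks + embedding) and returns the
#' classifier score per site.
#'
#' @param model a `phospho_model` from [run_pipeline()].
#' @param proteins named character vector of sequences.
#' @param sites data.frame with protein_id, position, residue (label
#'   optional).
#' @return the `sites` data.frame with an added `score` column.
#' @export
predict_sites <- function(model, proteins, sites) {
  if (is.null(sites$label)) sites$label <- "negative"  # placeholder for extraction
  frags <- extract_fragments(proteins, sites, model$config$flank)
  full <- .full_feature_block(frags$sequence, model$config$encoder,
                              model$embedding)
  X <- full$values[, model$selected_features, drop = FALSE]
  sites$score <- predict(model$classifier, X)
  sites
}
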