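# End-to-end orchestration: synth -> (keyword filter) -> debias -> score ->
# emotions -> report, with one config, per-stage count logging and seeded
# reproducibility.

#' Pipeline configuration
#'
#' All thresholds, weights and seeds of the pipeline in one validated list.
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param seed master seed (propagated to the generator).
#' @param root_terms keyword-filter root terms.
#' @param apply_keyword_filter filter the corpus on root terms.
#' @param drop_retweets drop retweets before analysis (kept by default).
#' @param generator list of [generator_config()] overrides.
#' @param debias list of [debias_config()] overrides.
#' @param neutral_band neutral band of the rule engine.
#' @param input_corpus optional path to an existing JSONL corpus; when set
#'   the generator stage is skipped.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            root_terms = default_root_terms(),
                            apply_keyword_filter = TRUE,
                            drop_retweets = FALSE,
                            generator = list(),
                            debias = list(),
                            neutral_band = NEUTRAL_BAND,
                            input_corpus = NULL) {
  cfg <- as.list(environment())
  cfg$generator <- do.call(generator_config,
                           utils::modifyList(list(seed = seed), generator))
  cfg$debias <- do.call(debias_config, debias)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$generator)) {
    bad <- setdiff(names(y$generator), names(formals(generator_config)))
    if (length(bad))
      stop("unknown generator keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(y$debias)) {
    bad <- setdiff(names(y$debias), names(formals(debias_config)))
    if (length(bad))
      stop("unknown debias keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Generates (or reads) a corpus, optionally keyword-filters it, debiases
#' it, scores sentiment, tags emotions, and writes summaries plus a
#' provenance log into `out_dir`. Deterministic for a given config.
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created if missing); NULL keeps everything
#'   in memory only.
#' @return list: corpora (raw, clean, bots_only, marketing_only), scores,
#'   tags, summaries (debiased, biased), comparison, debias report,
#'   provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  log_stage <- function(name, n_in, n_out)
    stages[[name]] <<- list(n_in = n_in, n_out = n_out)

  raw <- if (!is.null(config$input_corpus)) {
    read_corpus(config$input_corpus)
  } else {
    generate_corpus(config$generator)
  }
  log_stage("collect", n_tweets(raw), n_tweets(raw))

  work <- raw
  if (config$apply_keyword_filter) {
    work <- keyword_filter(work, config$root_terms)
    log_stage("keyword_filter", n_tweets(raw), n_tweets(work))
  }
  if (config$drop_retweets) {
    n0 <- n_tweets(work)
    work <- subset_corpus(work, !work$tweets$is_retweet)
    log_stage("drop_retweets", n0, n_tweets(work))
  }

  pp <- preprocess_corpus(work)
  scores_all <- score_corpus(work, pp = pp,
                             neutral_band = config$neutral_band)
  db <- debias_corpus(work, config$debias, pp = pp, scores = scores_all)
  log_stage("debias", n_tweets(work), n_tweets(db$clean))

  tags_all <- tag_corpus(work, scores_all, pp = pp)
  rownames(tags_all) <- tags_all$tweet_id

  subset_rows <- function(corp) {
    ids <- corp$tweets$tweet_id
    list(scores = scores_all[match(ids, scores_all$tweet_id), ],
         tags = tags_all[match(ids, tags_all$tweet_id), ])
  }
  clean_rows <- subset_rows(db$clean)
  # biased comparison corpus: humans + bots, marketing excluded
  biased <- subset_corpus(work,
                          !work$tweets$tweet_id %in%
                            db$marketing_only$tweets$tweet_id)
  biased_rows <- subset_rows(biased)

  sum_debiased <- summarize_corpus(clean_rows$scores$label, clean_rows$tags,
                                   "debiased")
  sum_biased <- summarize_corpus(biased_rows$scores$label, biased_rows$tags,
                                 "biased")
  comparison <- compare_summaries(sum_debiased, sum_biased)
  log_stage("report", n_tweets(db$clean), n_tweets(db$clean))

  provenance <- list(
    schema_version = "1.0",
    seed = config$seed,
    stages = stages,
    debias_report = unclass(db$report)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_corpus(raw, file.path(out_dir, "corpus_raw.jsonl"))
    if (!is.null(raw$truth))
      write_ground_truth(raw, file.path(out_dir, "truth.csv"))
    write_corpus(db$clean, file.path(out_dir, "corpus_debiased.jsonl"))
    write_corpus(db$bots_only, file.path(out_dir, "corpus_bots.jsonl"))
    write_corpus(db$marketing_only, file.path(out_dir, "corpus_marketing.jsonl"))
    utils::write.csv(scores_all, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(tags_all, file.path(out_dir, "emotions.csv"),
                     row.names = FALSE)
    write_summary(sum_debiased, file.path(out_dir, "summary_debiased.json"))
    write_summary(sum_biased, file.path(out_dir, "summary_biased.json"))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(raw = raw, clean = db$clean, bots_only = db$bots_only,
       marketing_only = db$marketing_only, account_scores = db$account_scores,
       scores = scores_all, tags = tags_all,
       summary_debiased = sum_debiased, summary_biased = sum_biased,
       comparison = comparison, report = db$report,
       provenance = provenance)
}
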