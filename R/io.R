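#' Write a design to CSV
#'
#' One row per displayed attribute, columns `version`, `task`, `position`,
#' `item_id`; comma-separated, UTF-8, header mandatory. A design with 3
#' versions of 16 tasks of 6 items yields 288 data rows.
#'
#' @param design A [`bws_design`][generate_design()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bws_design"))
  rows <- do.call(rbind, lapply(seq_len(design$n_versions), function(v) {
    tasks <- design$versions[[v]]
    data.frame(version = v,
               task = rep(seq_len(nrow(tasks)), ncol(tasks)),
               position = rep(seq_len(ncol(tasks)), each = nrow(tasks)),
               item_id = as.vector(tasks))
  }))
  rows <- rows[order(rows$version, rows$task, rows$position), ]
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a design from CSV
#'
#' Reads the format written by [write_design()] and re-validates the
#' structure (integer cells, no duplicate `(version, task, position)`,
#' no duplicate item within a task).
#'
#' @param path CSV path with header `version,task,position,item_id`.
#' @param n_items Number of items in the study; defaults to the largest
#'   item id present.
#' @return A [`bws_design`][generate_design()] object.
#' @export
read_design <- function(path, n_items = NULL) {
  df <- read.csv(path)
  need <- c("version", "task", "position", "item_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file is missing column(s): ", paste(miss, collapse = ", "))
  for (cl in need) {
    v <- df[[cl]]
    iv <- suppressWarnings(as.integer(v))
    nv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(iv) | is.na(nv) | iv != nv)
    if (length(bad))
      stop("non-integer value in column '", cl, "' (line ", bad[1L] + 1L,
           ")")
    df[[cl]] <- iv
  }
  key <- paste(df$version, df$task, df$position)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1L] + 1L
    stop("duplicate (version, task, position) at line ", line)
  }
  if (is.null(n_items)) n_items <- max(df$item_id)
  versions <- sort(unique(df$version))
  n_tasks <- max(df$task)
  set_size <- max(df$position)
  vlist <- lapply(versions, function(v) {
    sub <- df[df$version == v, ]
    m <- matrix(NA_integer_, n_tasks, set_size,
                dimnames = list(task = seq_len(n_tasks),
                                position = seq_len(set_size)))
    m[cbind(sub$task, sub$position)] <- sub$item_id
    if (anyNA(m)) stop("version ", v, " has missing task/position cells")
    m
  })
  design <- structure(
    list(n_items = as.integer(n_items), set_size = as.integer(set_size),
         n_tasks = as.integer(n_tasks), n_versions = length(versions),
         versions = vlist, pair_ss = NA_real_, min_pair_ss = NA_real_,
         r = (n_tasks * set_size) %/% n_items,
         seed = NA_integer_, n_iterations = NA_integer_),
    class = "bws_design")
  validate_design(design)
  design
}

#' Write responses to CSV
#'
#' Long format, one row per task per respondent: `respondent_id`, `cohort`,
#' `gender`, `version`, `task`, `best_item`, `worst_item`.
#'
#' @param responses A [`bws_responses`][simulate_responses()] data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_responses <- function(responses, path) {
  write.csv(as.data.frame(responses), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read responses from CSV and cross-validate against the design
#'
#' Checks that every picked item was shown in the referenced task, that best
#' and worst picks differ, and that every respondent answered the full set
#' of tasks; respondents with incomplete task sets are reported and dropped
#' (complete-case rule).
#'
#' @param path Long-format CSV as written by [write_responses()].
#' @param design The matching [`bws_design`][generate_design()].
#' @return A [`bws_responses`][simulate_responses()] data frame.
#' @export
read_responses <- function(path, design) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "version", "task", "best_item", "worst_item")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("response file is missing column(s): ",
         paste(miss, collapse = ", "))
  same <- df$best_item == df$worst_item
  if (any(same))
    stop("best and worst picks coincide at line ",
         which(same)[1L] + 1L, " (respondent ",
         df$respondent_id[which(same)[1L]], ")")
  if (any(!df$version %in% seq_len(design$n_versions)))
    stop("unknown questionnaire version: ",
         paste(unique(df$version[!df$version %in%
                                   seq_len(design$n_versions)]),
               collapse = ", "))
  prep <- prepare_choice_data(df, design, drop_incomplete = TRUE)
  df <- df[df$respondent_id %in% prep$ids, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("bws_responses", "data.frame"),
            n_items = design$n_items)
}

#' Run the full valuation pipeline
#'
#' Executes design generation, response simulation, hierarchical Bayes
#' estimation, root-likelihood filtering, relative importance scoring,
#' cohort comparison, jackknife regression and weight-set construction in
#' order, writing each stage's output as CSV into `out_dir` together with a
#' JSON manifest (`manifest.json`) recording the seed, the stage
#' parameters and the MD5 hash of every output file, so that identical
#' configurations give byte-identical runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; stage seeds are derived from it.
#' @param population A [population_config()]; its seed is overridden by
#'   `seed`.
#' @param design_args List of arguments for [generate_design()] (defaults
#'   to the study configuration 16 items / 6 per task / 16 tasks / 3
#'   versions).
#' @param mcmc A [mcmc_config()]; its seed is overridden by `seed`.
#' @param jackknife One of `"ols"` (regress the estimated scores directly,
#'   jackknifing the regression only), `"hb"` (full leave-one-out
#'   re-estimation of the choice model; expensive) or `"none"`.
#' @param threshold Root-likelihood exclusion threshold.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         population = population_config(),
                         design_args = list(n_items = 16, set_size = 6,
                                            n_tasks = 16, n_versions = 3,
                                            n_iterations = 100),
                         mcmc = mcmc_config(n_burn = 2000, n_keep = 2000),
                         jackknife = c("ols", "hb", "none"),
                         threshold = 0.2) {
  jackknife <- match.arg(jackknife)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  population$seed <- seed
  mcmc$seed <- seed + 1L

  design <- do.call(generate_design, c(design_args, list(seed = seed + 2L)))
  write_design(design, file.path(out_dir, "design.csv"))

  truth <- simulate_population(population)
  responses <- simulate_responses(design, truth, seed = seed + 3L)
  write_responses(responses, file.path(out_dir, "responses.csv"))

  posterior <- fit_hb(responses, design, mcmc)
  keep <- filter_inconsistent(posterior, threshold)
  post_df <- data.frame(respondent_id = posterior$ids,
                        rlh = unname(posterior$rlh),
                        included = posterior$ids %in% keep$included)
  post_df <- cbind(post_df,
                   setNames(as.data.frame(posterior$beta_mean),
                            paste0("beta_", seq_len(posterior$n_items))))
  write.csv(post_df, file.path(out_dir, "posterior.csv"),
            row.names = FALSE, quote = TRUE)

  ris <- compute_ris(posterior, include = keep$included)
  spec <- oxcap_mh_spec()
  ris_df <- data.frame(item_id = spec$items$item_number,
                       label = spec$items$label,
                       ris_mean = unname(ris$ris_mean),
                       ris_sd = unname(ris$ris_sd),
                       rank = ris$rank)
  write.csv(ris_df, file.path(out_dir, "ris.csv"), row.names = FALSE,
            quote = TRUE)
  ris_ind <- data.frame(respondent_id = rownames(ris$ris_individual),
                        ris$ris_individual, check.names = FALSE)
  names(ris_ind)[-1L] <- paste0("ris_", seq_len(ncol(ris$ris_individual)))
  write.csv(ris_ind, file.path(out_dir, "ris_individual.csv"),
            row.names = FALSE, quote = TRUE)

  cov <- ris$covariates[match(rownames(ris$ris_individual),
                              ris$covariates$respondent_id), ]
  comp <- cohort_rank_table(ris$ris_individual, cov$cohort)
  write.csv(comp, file.path(out_dir, "cohort_ranks.csv"), row.names = FALSE,
            quote = TRUE)
  pm <- pearson_matrix(ris$ris_individual)
  write.csv(data.frame(item = seq_len(nrow(pm)), pm, check.names = FALSE),
            file.path(out_dir, "correlations.csv"), row.names = FALSE,
            quote = FALSE)

  if (jackknife != "none") {
    fitter <- if (jackknife == "ols")
      ols_fitter(ris$ris_individual, cov)
    else
      hb_fitter(responses, design, mcmc, threshold)
    jk <- jackknife_robust(fitter, rownames(ris$ris_individual))
    tab <- significance_table(jk, ris, labels = spec$items$label)
    write.csv(tab, file.path(out_dir, "regression.csv"), row.names = FALSE,
              quote = TRUE)
  }

  ws <- build_weight_set(ris$ris_mean, spec)
  write_weight_set(ws, file.path(out_dir, "weights.csv"))

  files <- list.files(out_dir, pattern = "\\.csv$")
  manifest <- list(
    package_version = as.character(utils::packageVersion("capbws")),
    seed = seed,
    n_respondents = length(posterior$ids),
    n_included = length(keep$included),
    jackknife = jackknife,
    design = design_args,
    mcmc = mcmc[c("n_burn", "n_keep", "thinning")],
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
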