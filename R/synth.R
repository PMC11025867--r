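# Synthetic multi-modality cohort generator with planted ceRNA sponge axes.
#
# The generator emulates the statistical structure of a PAM50-stratified
# breast-cancer study: two circRNA cohorts and two miRNA/mRNA cohorts that
# share the same planted signals but carry independent noise, subtype-graded
# effect sizes that increase from normal-like to basal-like disease,
# inverse circRNA<->miRNA and positive circRNA<->mRNA coupling on planted
# axes, decoy interaction-table entries, a PPI graph with a high-score
# planted community, and survival times whose hazard depends on designated
# risk genes.

#' PAM50 intrinsic subtype labels in canonical aggressiveness order
#'
#' Returns the five PAM50 subtype labels ordered from least to most
#' aggressive disease: normal-like, Luminal A, Luminal B, HER2-enriched,
#' basal-like.  This ordering is fixed throughout the package: effect
#' gradients, subtype-trend profiles and the pan-flute filter all index
#' subtypes in this order.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' pam50_subtypes()
pam50_subtypes <- function() {
  c("NormalLike", "LumA", "LumB", "HER2", "Basal")
}

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that drives [generate_cohort()]
#' and its companions.  Defaults define a reduced-scale cohort: 80 control
#' samples and 80 tumor samples per PAM50 subtype per dataset, 150 circRNA,
#' 150 miRNA and 300 mRNA features, and 3 planted sponge axes whose log2
#' fold change grows from 0.5 (normal-like) to 3 (basal-like).  The group
#' size is set by a power calculation (see the package vignette): the
#' weakest planted effect (0.5 at normal-like, feature SD inflated to
#' about 0.56 by sponge coupling) must clear the effective
#' Benjamini-Hochberg cut of roughly 2e-4 (alpha 0.01, rank 3 of 150
#' features) with a three-sigma estimation margin, which requires about
#' 112 samples per group; the default is 120.
#'
#' @param n_control Number of control samples per dataset.
#' @param n_per_subtype Named integer vector (one entry per PAM50 subtype,
#'   see [pam50_subtypes()]) of tumor samples per subtype, or a single
#'   integer recycled to all five.
#' @param n_features Named integer vector with entries `circRNA`, `miRNA`,
#'   `mRNA`: number of features per modality.
#' @param n_planted_axes Number of planted (circRNA, miRNA, gene) axes;
#'   axes are feature-disjoint.
#' @param effect_gradient Non-negative, non-decreasing numeric vector of
#'   length 5: the true |log2FC| of planted features in each subtype,
#'   ordered normal-like to basal-like.  Non-decreasing by construction so
#'   planted axes satisfy the pan-flute criterion.
#' @param coupling_strength Weight in \[0, 1\] with which the circRNA
#'   residual of a planted axis is propagated into its sponged miRNA
#'   (negatively) and target gene (positively).  Coupling acts on the
#'   noise component only, so subtype mean shifts remain exactly
#'   `effect_gradient`.
#' @param decoy_interactions_per_true Number of decoy rows added to the
#'   interaction tables per true pair.  Decoys connect exactly one planted
#'   and one non-planted feature, so no decoy path is free of pure-noise
#'   features.
#' @param noise_sd Standard deviation of the Gaussian log2-scale noise.
#' @param baseline_log_mean Baseline log2 expression of every feature.
#' @param library_size Target library size for the optional count-mode
#'   mRNA matrices (Poisson sampling of log-normal means).
#' @param count_mode If `TRUE`, additionally emit integer count matrices
#'   for the mRNA modality (for testing count-based normalization).
#' @param survival_baseline_hazard Baseline hazard of the exponential
#'   survival model.
#' @param survival_beta Log hazard ratio per standard deviation of risk
#'   gene expression.
#' @param censor_rate Expected fraction of censored samples in \[0, 1).
#' @param ppi_background_prob Edge probability of the Erdos-Renyi
#'   background in [generate_ppi()].
#' @param ppi_background_score_range Score range of background PPI edges;
#'   the default upper bound 0.4 sits at the canonical STRING loading
#'   threshold, so the default background is removed by `load_ppi(...,
#'   score_threshold = 0.4)`.
#' @param ppi_community_score_range Score range of planted-community PPI
#'   edges.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_cohort()], [simulate_cohort()]
#' @export
synth_config <- function(n_control = 120L,
                         n_per_subtype = 120L,
                         n_features = c(circRNA = 150L, miRNA = 150L, mRNA = 300L),
                         n_planted_axes = 3L,
                         effect_gradient = c(0.5, 1, 1.5, 2, 3),
                         coupling_strength = 0.5,
                         decoy_interactions_per_true = 5L,
                         noise_sd = 0.5,
                         baseline_log_mean = 8,
                         library_size = 1e6,
                         count_mode = FALSE,
                         survival_baseline_hazard = 0.1,
                         survival_beta = 1,
                         censor_rate = 0.3,
                         ppi_background_prob = 0.05,
                         ppi_background_score_range = c(0.05, 0.4),
                         ppi_community_score_range = c(0.85, 0.99),
                         seed = 1L) {
  subtypes <- pam50_subtypes()
  if (length(n_per_subtype) == 1L) {
    n_per_subtype <- stats::setNames(rep(as.integer(n_per_subtype), 5L), subtypes)
  }
  cfg <- list(
    n_control = as.integer(n_control),
    n_per_subtype = n_per_subtype,
    n_features = n_features,
    n_planted_axes = as.integer(n_planted_axes),
    effect_gradient = as.numeric(effect_gradient),
    coupling_strength = coupling_strength,
    decoy_interactions_per_true = as.integer(decoy_interactions_per_true),
    noise_sd = noise_sd,
    baseline_log_mean = baseline_log_mean,
    library_size = library_size,
    count_mode = isTRUE(count_mode),
    survival_baseline_hazard = survival_baseline_hazard,
    survival_beta = survival_beta,
    censor_rate = censor_rate,
    ppi_background_prob = ppi_background_prob,
    ppi_background_score_range = ppi_background_score_range,
    ppi_community_score_range = ppi_community_score_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  subtypes <- pam50_subtypes()
  if (!identical(sort(names(cfg$n_per_subtype)), sort(subtypes))) {
    stop("n_per_subtype must be named with exactly the five PAM50 subtypes")
  }
  if (any(cfg$n_per_subtype < 2L) || cfg$n_control < 2L) {
    stop("every sample group must contain at least 2 samples")
  }
  if (!all(c("circRNA", "miRNA", "mRNA") %in% names(cfg$n_features))) {
    stop("n_features must name circRNA, miRNA and mRNA")
  }
  if (length(cfg$effect_gradient) != 5L || any(cfg$effect_gradient < 0)) {
    stop("effect_gradient must be 5 non-negative values (NormalLike ... Basal)")
  }
  if (any(diff(cfg$effect_gradient) < 0)) {
    stop("effect_gradient must be non-decreasing from NormalLike to Basal")
  }
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]")
  }
  if (cfg$decoy_interactions_per_true < 0L) {
    stop("decoy_interactions_per_true must be >= 0")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (cfg$survival_baseline_hazard <= 0) {
    stop("survival_baseline_hazard must be > 0")
  }
  needed <- 3L * cfg$n_planted_axes  # disjoint features per modality pair
  if (cfg$n_planted_axes > 0L &&
      (cfg$n_features[["circRNA"]] < cfg$n_planted_axes ||
       cfg$n_features[["miRNA"]] < cfg$n_planted_axes ||
       cfg$n_features[["mRNA"]] < cfg$n_planted_axes)) {
    stop("each modality needs at least n_planted_axes features")
  }
  invisible(cfg)
}

feature_ids <- function(cfg) {
  list(
    circRNA = sprintf("circ_%04d", seq_len(cfg$n_features[["circRNA"]])),
    miRNA   = sprintf("mir_%04d",  seq_len(cfg$n_features[["miRNA"]])),
    mRNA    = sprintf("gene_%04d", seq_len(cfg$n_features[["mRNA"]]))
  )
}

#' Generate a synthetic multi-modality cohort with planted sponge axes
#'
#' Draws two dataset replicates (independent cohorts sharing the same
#' ground truth but not the same noise) of circRNA, miRNA and mRNA log2
#' expression matrices together with sample metadata and a [truth
#' ledger][generate_cohort] (`TruthSet`).  Control samples are drawn
#' around `baseline_log_mean`; tumor samples of subtype *k* are shifted by
#' `+/- effect_gradient[k]` on planted features, with the sign given by
#' each axis' direction pattern (`up-down-up`: circRNA and gene up, miRNA
#' down; `down-up-down`: the reverse).  The circRNA residual of each
#' planted axis is propagated into its miRNA (weight
#' `-coupling_strength`) and gene (`+coupling_strength`), inducing the
#' inverse sponge correlation without changing group means.  Non-planted
#' features are pure noise.
#'
#' @param config A [synth_config()].
#' @return A list of class `cerna_cohort` with elements
#'   \describe{
#'     \item{datasets}{list of two replicates, each with `expr` (named list
#'       of feature x sample matrices per modality, plus `mRNA_counts`
#'       when `count_mode`) and `meta` (data.frame with `sample_id`,
#'       `group`, `subtype`).}
#'     \item{truth}{the `TruthSet`: `planted_axes` data.frame (circRNA,
#'       miRNA, gene, direction_pattern), `risk_genes` data.frame (gene,
#'       sign), `true_lfc` feature x subtype matrix of true log2 fold
#'       changes, and later `decoy_pairs` once
#'       [generate_interaction_tables()] has run.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  subtypes <- pam50_subtypes()
  ids <- feature_ids(config)
  nax <- config$n_planted_axes

  # planted features: axis i uses the i-th sampled feature of each modality
  planted <- data.frame(
    circRNA = sample(ids$circRNA, nax),
    miRNA   = sample(ids$miRNA, nax),
    gene    = sample(ids$mRNA, nax),
    direction_pattern = rep(c("up-down-up", "down-up-down"), length.out = nax),
    stringsAsFactors = FALSE
  )
  if (nax == 0L) planted <- planted[0, ]

  # true per-feature, per-subtype log2FC ledger (all modalities stacked)
  all_feats <- c(ids$circRNA, ids$miRNA, ids$mRNA)
  true_lfc <- matrix(0, nrow = length(all_feats), ncol = 5L,
                     dimnames = list(all_feats, subtypes))
  if (nax > 0L) {
    for (i in seq_len(nax)) {
      s <- if (planted$direction_pattern[i] == "up-down-up") 1 else -1
      true_lfc[planted$circRNA[i], ] <-  s * config$effect_gradient
      true_lfc[planted$miRNA[i], ]   <- -s * config$effect_gradient
      true_lfc[planted$gene[i], ]    <-  s * config$effect_gradient
    }
  }

  groups <- c(rep("control", config$n_control),
              rep(subtypes, times = config$n_per_subtype[subtypes]))
  subtype_col <- c(rep(NA_character_, config$n_control),
                   rep(subtypes, times = config$n_per_subtype[subtypes]))
  n_samp <- length(groups)

  gen_dataset <- function(d) {
    sample_id <- sprintf("D%d_S%03d", d, seq_len(n_samp))
    meta <- data.frame(sample_id = sample_id,
                       group = ifelse(groups == "control", "control", "tumor"),
                       subtype = subtype_col,
                       stringsAsFactors = FALSE)
    # per-subtype shift column index for each sample (0 for controls)
    shift_of <- function(feat) {
      out <- numeric(n_samp)
      tum <- !is.na(subtype_col)
      out[tum] <- true_lfc[feat, subtype_col[tum]]
      out
    }
    expr <- list()
    noise <- list()
    for (mod in c("circRNA", "miRNA", "mRNA")) {
      eps <- matrix(stats::rnorm(length(ids[[mod]]) * n_samp, 0, config$noise_sd),
                    nrow = length(ids[[mod]]),
                    dimnames = list(ids[[mod]], sample_id))
      m <- eps + config$baseline_log_mean
      m <- m + t(vapply(ids[[mod]], shift_of, numeric(n_samp)))
      expr[[mod]] <- m
      noise[[mod]] <- eps
    }
    # sponge coupling: circRNA residual leaks into miRNA (-) and gene (+)
    if (nax > 0L && config$coupling_strength > 0) {
      for (i in seq_len(nax)) {
        eps_c <- noise$circRNA[planted$circRNA[i], ]
        expr$miRNA[planted$miRNA[i], ] <-
          expr$miRNA[planted$miRNA[i], ] - config$coupling_strength * eps_c
        expr$mRNA[planted$gene[i], ] <-
          expr$mRNA[planted$gene[i], ] + config$coupling_strength * eps_c
      }
    }
    if (config$count_mode) {
      mu <- 2^expr$mRNA
      lambda <- sweep(mu, 2, colSums(mu), "/") * config$library_size
      cnt <- matrix(stats::rpois(length(lambda), lambda),
                    nrow = nrow(lambda), dimnames = dimnames(lambda))
      expr$mRNA_counts <- cnt
    }
    list(expr = expr, meta = meta)
  }

  datasets <- list(gen_dataset(1L), gen_dataset(2L))
  risk_genes <- if (nax > 0L) {
    data.frame(gene = planted$gene, sign = 1, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), sign = numeric())
  }
  truth <- list(planted_axes = planted,
                decoy_pairs = NULL,
                risk_genes = risk_genes,
                true_lfc = true_lfc)
  structure(list(datasets = datasets, truth = truth, config = config),
            class = "cerna_cohort")
}

#' Generate knowledge-base interaction tables with decoys
#'
#' Emits the two directed interaction tables (circRNA to miRNA, miRNA to
#' gene) that stand in for knowledge-base lookups.  Every planted pair is
#' present; `decoy_interactions_per_true` decoys are added per true pair.
#' Each decoy connects exactly one planted feature with one non-planted
#' feature (so decoy paths always contain a pure-noise member, and no
#' decoy links two planted features of any axis).
#'
#' @param truth `TruthSet` from [generate_cohort()].
#' @param config The same [synth_config()].
#' @return List with `circ_mir` and `mir_gene` data.frames (`source`,
#'   `target`) and `decoy_pairs` (both tables' decoys, with a `table`
#'   column).
#' @export
generate_interaction_tables <- function(truth, config) {
  set.seed(config$seed + 101L)
  ids <- feature_ids(config)
  planted <- truth$planted_axes
  ndecoy <- config$decoy_interactions_per_true

  draw_decoys <- function(true_pairs, src_pool, tgt_pool) {
    planted_src <- unique(true_pairs$source)
    planted_tgt <- unique(true_pairs$target)
    free_src <- setdiff(src_pool, planted_src)
    free_tgt <- setdiff(tgt_pool, planted_tgt)
    out <- list()
    key <- paste(true_pairs$source, true_pairs$target)
    for (i in seq_len(nrow(true_pairs))) {
      for (j in seq_len(ndecoy)) {
        repeat {
          if (stats::runif(1) < 0.5 && length(free_tgt) > 0L) {
            cand <- c(true_pairs$source[i], sample(free_tgt, 1L))
          } else {
            cand <- c(sample(free_src, 1L), true_pairs$target[i])
          }
          k <- paste(cand[1], cand[2])
          if (!k %in% key) {
            key <- c(key, k)
            out[[length(out) + 1L]] <- cand
            break
          }
        }
      }
    }
    if (length(out) == 0L) {
      return(data.frame(source = character(), target = character()))
    }
    m <- do.call(rbind, out)
    data.frame(source = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
  }

  true_cm <- data.frame(source = planted$circRNA, target = planted$miRNA,
                        stringsAsFactors = FALSE)
  true_mg <- data.frame(source = planted$miRNA, target = planted$gene,
                        stringsAsFactors = FALSE)
  dec_cm <- draw_decoys(true_cm, ids$circRNA, ids$miRNA)
  dec_mg <- draw_decoys(true_mg, ids$miRNA, ids$mRNA)
  circ_mir <- rbind(true_cm, dec_cm)
  mir_gene <- rbind(true_mg, dec_mg)
  circ_mir <- circ_mir[order(circ_mir$source, circ_mir$target), , drop = FALSE]
  mir_gene <- mir_gene[order(mir_gene$source, mir_gene$target), , drop = FALSE]
  rownames(circ_mir) <- rownames(mir_gene) <- NULL
  decoys <- rbind(
    if (nrow(dec_cm)) cbind(dec_cm, table = "circ_mir") else NULL,
    if (nrow(dec_mg)) cbind(dec_mg, table = "mir_gene") else NULL
  )
  list(circ_mir = circ_mir, mir_gene = mir_gene, decoy_pairs = decoys)
}

#' Generate a synthetic weighted PPI edge list
#'
#' Wires the planted-axis genes into one connected high-score community (a
#' clique with scores in `ppi_community_score_range`) and adds
#' Erdos-Renyi background edges among the remaining gene pairs with
#' probability `ppi_background_prob` and scores in
#' `ppi_background_score_range`.  With the default background range (upper
#' bound 0.4) the canonical loading threshold `> 0.4` retains exactly the
#' community edges.
#'
#' @param genes Character vector of gene ids forming the node universe.
#' @param truth `TruthSet` from [generate_cohort()].
#' @param config The same [synth_config()].
#' @return data.frame with columns `node1`, `node2`, `score` (undirected,
#'   no self loops, no parallel edges).
#' @export
generate_ppi <- function(genes, truth, config) {
  if (length(genes) == 0L) stop("genes must be non-empty")
  set.seed(config$seed + 202L)
  community <- intersect(truth$planted_axes$gene, genes)
  edges <- list()
  if (length(community) >= 2L) {
    cmb <- utils::combn(sort(community), 2L)
    sc <- stats::runif(ncol(cmb), config$ppi_community_score_range[1],
                       config$ppi_community_score_range[2])
    edges$community <- data.frame(node1 = cmb[1, ], node2 = cmb[2, ],
                                  score = sc, stringsAsFactors = FALSE)
  }
  others <- utils::combn(sort(genes), 2L)
  in_comm <- others[1, ] %in% community & others[2, ] %in% community
  others <- others[, !in_comm, drop = FALSE]
  if (ncol(others) > 0L && config$ppi_background_prob > 0) {
    keep <- stats::runif(ncol(others)) < config$ppi_background_prob
    if (any(keep)) {
      bg <- others[, keep, drop = FALSE]
      sc <- stats::runif(ncol(bg), config$ppi_background_score_range[1],
                         config$ppi_background_score_range[2])
      edges$background <- data.frame(node1 = bg[1, ], node2 = bg[2, ],
                                     score = sc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, edges)
  if (is.null(out)) {
    out <- data.frame(node1 = character(), node2 = character(),
                      score = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Generate expression-linked survival outcomes
#'
#' Event times are exponential with per-sample hazard
#' `survival_baseline_hazard * exp(survival_beta * z_i)`, where `z_i` is
#' the sum of the signed standardized expressions of the risk genes (for
#' a single risk gene, `survival_beta` is therefore its true log hazard
#' ratio per standard deviation).  Censoring
#' is uniform on `[0, T]` with `T` calibrated numerically so that the
#' expected censored fraction equals `censor_rate`.
#'
#' @param expr Gene expression matrix (genes x samples) from which risk
#'   gene expression is read.
#' @param truth `TruthSet` holding `risk_genes` (data.frame `gene`,
#'   `sign`).
#' @param config The same [synth_config()].
#' @return data.frame with `sample_id`, `time`, `event` (1 = event,
#'   0 = censored).
#' @export
generate_survival <- function(expr, truth, config) {
  rg <- truth$risk_genes
  if (nrow(rg) > 0L && !all(rg$gene %in% rownames(expr))) {
    stop("unknown risk gene id: ",
         paste(setdiff(rg$gene, rownames(expr)), collapse = ", "))
  }
  set.seed(config$seed + 303L)
  n <- ncol(expr)
  if (nrow(rg) > 0L) {
    z <- vapply(seq_len(nrow(rg)), function(i) {
      v <- expr[rg$gene[i], ]
      rg$sign[i] * (v - mean(v)) / stats::sd(v)
    }, numeric(n))
    if (is.null(dim(z))) z <- matrix(z, nrow = n)
    eta <- config$survival_beta * rowSums(z)
  } else {
    eta <- rep(0, n)
  }
  haz <- config$survival_baseline_hazard * exp(eta)
  x <- stats::rexp(n, rate = haz)
  if (config$censor_rate > 0) {
    # E[censored fraction] for uniform C ~ U(0, T): mean_i (1-exp(-h_i T))/(h_i T)
    cens_frac <- function(logT) {
      Tt <- exp(logT)
      mean((1 - exp(-haz * Tt)) / (haz * Tt))
    }
    f <- function(logT) cens_frac(logT) - config$censor_rate
    sol <- stats::uniroot(f, lower = log(1e-8 / max(haz)),
                          upper = log(1e8 / min(haz)), tol = 1e-10)
    Tmax <- exp(sol$root)
    cens <- stats::runif(n, 0, Tmax)
    time <- pmin(x, cens)
    event <- as.integer(x <= cens)
  } else {
    time <- x
    event <- rep(1L, n)
  }
  data.frame(sample_id = colnames(expr), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a complete pipeline-ready cohort
#'
#' Convenience wrapper: runs [generate_cohort()],
#' [generate_interaction_tables()], [generate_ppi()] (over the mRNA
#' universe) and [generate_survival()] (over the tumor samples of the
#' first dataset replicate), returning a single object accepted by
#' [run_pipeline()].
#'
#' @param config A [synth_config()].
#' @return A `cerna_cohort` with additional elements `interactions`,
#'   `ppi` and `survival`.
#' @export
simulate_cohort <- function(config) {
  cohort <- generate_cohort(config)
  cohort$interactions <- generate_interaction_tables(cohort$truth, config)
  cohort$truth$decoy_pairs <- cohort$interactions$decoy_pairs
  cohort$ppi <- generate_ppi(rownames(cohort$datasets[[1]]$expr$mRNA),
                             cohort$truth, config)
  meta1 <- cohort$datasets[[1]]$meta
  tumor <- meta1$sample_id[meta1$group == "tumor"]
  cohort$survival <- generate_survival(
    cohort$datasets[[1]]$expr$mRNA[, tumor, drop = FALSE],
    cohort$truth, config)
  cohort
}

#' Write a simulated cohort to plain-text files
#'
#' Writes expression TSVs (first column `feature`, remaining columns the
#' sample ids), metadata TSVs (`sample_id`, `group`, `subtype` and, for
#' dataset 1, `time`/`event`), interaction TSVs (`source`, `target`), the
#' PPI edge list (`node1`, `node2`, `score`) and the truth ledger as JSON.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  for (d in 1:2) {
    ds <- cohort$datasets[[d]]
    for (mod in names(ds$expr)) {
      df <- data.frame(feature = rownames(ds$expr[[mod]]),
                       ds$expr[[mod]], check.names = FALSE)
      wr(df, sprintf("dataset%d_%s.tsv", d, mod))
    }
    meta <- ds$meta
    if (d == 1L && !is.null(cohort$survival)) {
      meta <- merge(meta, cohort$survival, by = "sample_id",
                    all.x = TRUE, sort = FALSE)
    }
    wr(meta, sprintf("dataset%d_metadata.tsv", d))
  }
  if (!is.null(cohort$interactions)) {
    wr(cohort$interactions$circ_mir, "interactions_circ_mir.tsv")
    wr(cohort$interactions$mir_gene, "interactions_mir_gene.tsv")
  }
  if (!is.null(cohort$ppi)) wr(cohort$ppi, "ppi_edges.tsv")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted_axes = cohort$truth$planted_axes,
         risk_genes = cohort$truth$risk_genes,
         true_lfc = as.data.frame(cohort$truth$true_lfc)),
    truth_path, dataframe = "columns", pretty = TRUE, digits = NA)
  files <- c(files, truth_path)
  invisible(files)
}
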