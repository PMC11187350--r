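#' Specification for a synthetic interactome with planted modules
#'
#' Defaults describe the benchmark condition used throughout the package:
#' a 500-node preferential-attachment graph of mean degree ~4 (sparse,
#' interactome-like), a 20-gene herb target module and a 10-gene symptom
#' module planted either proximally (within 1 hop of the herb set) or
#' distally (more than 3 hops away).
#'
#' @param n_nodes number of nodes (>= 2).
#' @param graph_model `"preferential_attachment"` or `"erdos_renyi"`.
#' @param model_param edges added per step (preferential attachment,
#'   default 2) or edge probability (Erdos-Renyi, default 0.01).
#' @param herb_size,symptom_size planted module sizes.
#' @param mode `"proximal"` or `"distal"`.
#' @param radius hop radius separating the two modes (>= 1); defaults to
#'   1 in proximal mode and 3 in distal mode.
#' @param seed integer seed; generators never touch global RNG state.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n_nodes = 500L,
                       graph_model = c("preferential_attachment",
                                       "erdos_renyi"),
                       model_param = NULL,
                       herb_size = 20L, symptom_size = 10L,
                       mode = c("proximal", "distal"),
                       radius = NULL,
                       seed = 1L) {
  graph_model <- match.arg(graph_model)
  mode <- match.arg(mode)
  if (is.null(model_param)) {
    model_param <- if (graph_model == "erdos_renyi") 0.01 else 2
  }
  if (is.null(radius)) {
    radius <- if (mode == "proximal") 1L else 3L
  }
  if (n_nodes < 2L) stop_input("n_nodes must be >= 2")
  if (radius < 1L) stop_input("radius must be >= 1")
  if (herb_size + symptom_size > n_nodes) {
    stop_input("herb_size + symptom_size exceeds n_nodes")
  }
  structure(list(n_nodes = as.integer(n_nodes), graph_model = graph_model,
                 model_param = model_param, herb_size = as.integer(herb_size),
                 symptom_size = as.integer(symptom_size), mode = mode,
                 radius = as.integer(radius), seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a synthetic interactome
#'
#' Seed-deterministic random graph with gene-symbol-like node names
#' (`G0001`, `G0002`, ...). The same spec always yields the same edge set.
#'
#' @param spec a [plant_spec()].
#' @return a `ppi_graph`.
#' @export
generate_ppi <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  if (spec$graph_model == "erdos_renyi" &&
      (spec$model_param < 0 || spec$model_param > 1)) {
    stop_input("erdos_renyi model_param must be a probability")
  }
  if (spec$graph_model == "preferential_attachment" && spec$model_param < 1) {
    stop_input("preferential_attachment model_param must be >= 1")
  }
  g <- with_seed(spec$seed, {
    switch(spec$graph_model,
           erdos_renyi = igraph::sample_gnp(spec$n_nodes, spec$model_param),
           preferential_attachment = igraph::sample_pa(
             spec$n_nodes, m = spec$model_param, directed = FALSE))
  })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(spec$n_nodes))
  g <- igraph::simplify(g)
  new_ppi_graph(g, report = list(n_lines = igraph::ecount(g),
                                 n_edges = igraph::ecount(g),
                                 n_self_loops = 0L, n_duplicates = 0L))
}

#' Plant herb and symptom gene sets in an interactome
#'
#' Samples the herb module from the largest connected component, then the
#' symptom module from nodes at hop distance in `[1, radius]` of the herb
#' set (proximal mode) or strictly greater than `radius` (distal mode).
#' The two sets are disjoint. If the candidate pool is smaller than
#' `symptom_size`, the closest (proximal) or farthest (distal) available
#' non-herb nodes top it up, with a warning.
#'
#' @param graph a `ppi_graph`.
#' @param spec a [plant_spec()]; its `seed` drives the sampling.
#' @return list with elements `herb` and `symptom`, both [gene_set()].
#' @export
plant_gene_sets <- function(graph, spec) {
  stopifnot(inherits(graph, "ppi_graph"), inherits(spec, "plant_spec"))
  comp <- igraph::components(graph$graph)
  big <- which.max(comp$csize)
  if (comp$csize[big] < spec$herb_size + spec$symptom_size) {
    stop_input("no connected component can host both planted modules")
  }
  comp_nodes <- ppi_nodes(graph)[comp$membership == big]
  with_seed(spec$seed, {
    herb_nodes <- sample(comp_nodes, spec$herb_size)
    d <- single_source_distances(graph, herb_nodes)
    d <- d[names(d) %in% comp_nodes]
    nonherb <- d[d > 0L]
    pool <- if (spec$mode == "proximal") {
      names(nonherb)[nonherb <= spec$radius]
    } else {
      names(nonherb)[nonherb > spec$radius]
    }
    if (length(pool) >= spec$symptom_size) {
      symptom_nodes <- sample(pool, spec$symptom_size)
    } else {
      warning("only ", length(pool), " candidate node(s) satisfy the ",
              spec$mode, " radius; topping up with ",
              if (spec$mode == "proximal") "nearest" else "farthest",
              " available nodes")
      rest <- setdiff(names(nonherb), pool)
      ord <- if (spec$mode == "proximal") order(nonherb[rest]) else
        order(-nonherb[rest])
      need <- spec$symptom_size - length(pool)
      symptom_nodes <- c(pool, rest[ord][seq_len(need)])
    }
    list(herb = gene_set("planted_herb", herb_nodes, "herb_target"),
         symptom = gene_set("planted_symptom", symptom_nodes,
                            "symptom_gene"))
  })
}

#' Specification for a synthetic patient cohort
#'
#' Defaults emulate the study scale at a tractable size: a rare diagnosis
#' (~0.4% prevalence), herb usage far more likely under the diagnosis
#' (39%) than otherwise (8%), and symptom relief more likely in the
#' used arm.
#'
#' @param n_patients cohort size (>= 1).
#' @param p_disease probability of carrying `disease_label`.
#' @param p_usage_given_disease,p_usage_given_other usage probabilities by
#'   diagnosis arm.
#' @param symptom_prevalence named numeric vector: admission probability
#'   per symptom term (applies to diseased patients).
#' @param relief_prob_used,relief_prob_unused named numeric vectors:
#'   probability a present symptom is relieved, by usage arm; names must
#'   match `symptom_prevalence`.
#' @param disease_label diagnosis string for the case group.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20000L,
                        p_disease = 0.004,
                        p_usage_given_disease = 0.39,
                        p_usage_given_other = 0.08,
                        symptom_prevalence = c(cough = 0.6, asthenia = 0.3,
                                               "chest pain" = 0.25),
                        relief_prob_used = c(cough = 0.33, asthenia = 0.16,
                                             "chest pain" = 0.61),
                        relief_prob_unused = c(cough = 0.28, asthenia = 0.31,
                                               "chest pain" = 0.35),
                        disease_label = "LUAD",
                        seed = 1L) {
  probs <- c(p_disease, p_usage_given_disease, p_usage_given_other,
             symptom_prevalence, relief_prob_used, relief_prob_unused)
  if (any(probs < 0 | probs > 1)) {
    stop_input("all probabilities must lie in [0, 1]")
  }
  if (n_patients < 1L) stop_input("n_patients must be >= 1")
  syms <- names(symptom_prevalence)
  if (!setequal(syms, names(relief_prob_used)) ||
      !setequal(syms, names(relief_prob_unused))) {
    stop_input("relief probability names must match symptom_prevalence")
  }
  structure(list(n_patients = as.integer(n_patients), p_disease = p_disease,
                 p_usage_given_disease = p_usage_given_disease,
                 p_usage_given_other = p_usage_given_other,
                 symptom_prevalence = symptom_prevalence,
                 relief_prob_used = relief_prob_used[syms],
                 relief_prob_unused = relief_prob_unused[syms],
                 disease_label = disease_label, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Diagnosis is Bernoulli(`p_disease`); usage is Bernoulli conditioned on
#' the diagnosis arm; each symptom is present at admission independently
#' with its prevalence (diseased patients only — the non-case bulk carries
#' no symptom data, mirroring an analysis focused on one disease group);
#' a present symptom is relieved with the arm-specific probability.
#' Seed-deterministic.
#'
#' @param spec a [cohort_spec()].
#' @return a cohort data.frame (see [cohort-schema]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  syms <- names(spec$symptom_prevalence)
  with_seed(spec$seed, {
    diseased <- stats::runif(n) < spec$p_disease
    p_use <- ifelse(diseased, spec$p_usage_given_disease,
                    spec$p_usage_given_other)
    used <- stats::runif(n) < p_use
    age <- pmax(18, round(stats::rnorm(n, 66.5, 10)))
    sex <- ifelse(stats::runif(n) < 0.62, "male", "female")
    los <- round(pmax(1, stats::rgamma(n, shape = 4, scale = 3.7)), 1)
    admission <- vector("list", n)
    relieved <- vector("list", n)
    admission[] <- list(character(0))
    relieved[] <- list(character(0))
    idx <- which(diseased)
    for (i in idx) {
      present <- syms[stats::runif(length(syms)) <
                        spec$symptom_prevalence]
      p_rel <- if (used[i]) spec$relief_prob_used[present] else
        spec$relief_prob_unused[present]
      rel <- present[stats::runif(length(present)) < p_rel]
      admission[[i]] <- present
      relieved[[i]] <- rel
    }
    as_cohort(data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      age = age, sex = sex,
      diagnosis = ifelse(diseased, spec$disease_label, "other"),
      los = los, used_herb = used,
      admission_symptoms = I(admission),
      relieved_symptoms = I(relieved),
      stringsAsFactors = FALSE))
  })
}
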