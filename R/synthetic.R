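#' Default developmental time points for synthetic atlases
#'
#' Two gestational and ten postnatal ages spanning 21 weeks of gestation to
#' 23 postnatal years, mirroring the span retained by the analysis.
#'
#' @return character vector of age labels.
#' @export
default_ages <- function() {
  c("21wg", "24wg", "4mo", "6mo", "1y", "2y", "4y", "8y", "13y", "18y", "23y")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic RPKM atlas
#'
#' Defines the planted structure of a generated atlas: disjoint gene
#' classes with known truth. Defaults mirror the calibration conditions of
#' the analysis: 21 constantly expressed housekeeping genes whose global
#' tier span is at most 3 by construction, planted highly expressed genes
#' (max RPKM >= 60 in one to three regions), planted pan-region highly
#' expressed genes, and planted silent genes (all samples < 1 RPKM).
#' Remaining genes are detected background below the high threshold.
#'
#' @param n_genes total genes.
#' @param regions region codes (default: the canonical 11).
#' @param ages age labels (default: [default_ages()]).
#' @param n_housekeeping,n_high,n_silent,n_pan_region_high planted class sizes.
#' @param noise_sd multiplicative log-normal noise (sd on the log scale).
#' @param six_month_dip optional factor < 1 applied to the 6mo column of
#'   background and highly expressed genes, emulating a systematically low
#'   time point; 1 disables it.
#' @param seed RNG seed.
#' @return object of class \code{"atlas_spec"}.
#' @export
atlas_spec <- function(n_genes = 400, regions = canonical_regions(),
                       ages = default_ages(),
                       n_housekeeping = 21, n_high = 32, n_silent = 46,
                       n_pan_region_high = 9, noise_sd = 0.25,
                       six_month_dip = 1, seed = 1) {
  if (length(ages) == 0) stop_bt("at least one age is required")
  if (length(regions) == 0) stop_bt("at least one region is required")
  planted <- n_housekeeping + n_high + n_silent + n_pan_region_high
  if (planted > n_genes)
    stop_bt("planted classes (%d) exceed n_genes (%d)", planted, n_genes)
  if (six_month_dip <= 0 || six_month_dip > 1)
    stop_bt("six_month_dip must lie in (0, 1]")
  structure(list(n_genes = n_genes, regions = regions, ages = ages,
                 n_housekeeping = n_housekeeping, n_high = n_high,
                 n_silent = n_silent, n_pan_region_high = n_pan_region_high,
                 noise_sd = noise_sd, six_month_dip = six_month_dip,
                 seed = seed),
            class = "atlas_spec")
}

tier_edges <- function(scheme = tier_scheme()) {
  list(lo = c(0, scheme$boundaries), hi = c(scheme$boundaries, Inf))
}

# Simulate RPKM rows for a list of per-gene profiles.
# profile: list per gene with $gene, $class, optional $high_regions,
# $silent_regions. Assumes the RNG is already seeded by the caller.
simulate_profiles <- function(profiles, regions, ages, noise_sd = 0.25,
                              six_month_dip = 1, scheme = tier_scheme()) {
  samples_region <- rep(regions, each = length(ages))
  samples_age <- rep(ages, times = length(regions))
  S <- length(samples_region)
  edges <- tier_edges(scheme)
  hi_cap <- scheme$high_threshold - 0.5        # strictly below "high"
  det_floor <- scheme$detection_threshold + 0.05
  noisy <- function(loc) loc * exp(stats::rnorm(S, 0, noise_sd))
  bg_row <- function() pmin(pmax(noisy(exp(stats::runif(1, log(1.5), log(35)))),
                                 det_floor), hi_cap)
  rows <- lapply(profiles, function(p) {
    v <- switch(p$class,
      silent = pmin(noisy(stats::runif(1, 0.05, 0.4)),
                    scheme$detection_threshold - 0.05),
      housekeeping = {
        loc <- stats::runif(1, 5, 50)
        t0 <- rpkm_to_tier(loc, scheme)
        lo <- max(edges$lo[max(t0 - 1L, 1L)], det_floor)
        hi <- min(edges$hi[min(t0 + 1L, scheme$n_tiers)] - 0.5, hi_cap)
        pmin(pmax(noisy(loc), lo), hi)
      },
      bg_row())
    if (!is.null(p$high_regions) && length(p$high_regions) > 0) {
      for (r in p$high_regions) {
        idx <- which(samples_region == r)
        v[sample(idx, 1)] <- stats::runif(1, scheme$high_threshold + 5, 400)
      }
    }
    if (!is.null(p$silent_regions) && length(p$silent_regions) > 0) {
      idx <- samples_region %in% p$silent_regions
      v[idx] <- pmin(v[idx], scheme$detection_threshold - 0.05) *
        stats::runif(sum(idx), 0.5, 1)
    }
    v
  })
  m <- do.call(rbind, rows)
  if (six_month_dip < 1) {
    dip_cols <- samples_age == "6mo"
    dippable <- vapply(profiles, function(p)
      p$class %in% c("background", "high", "pan_region_high"), TRUE)
    m[dippable, dip_cols] <- m[dippable, dip_cols] * six_month_dip
    # a dipped sample must stay detected for background genes
    m[dippable, dip_cols] <- pmax(m[dippable, dip_cols], det_floor)
  }
  rownames(m) <- vapply(profiles, function(p) p$gene, "")
  expression_atlas(m, regions = samples_region, ages = samples_age)
}

#' Generate a synthetic atlas with planted truth
#'
#' Deterministic given the spec's seed. Planted guarantees (by clamping,
#' not by chance): housekeeping genes span at most 3 consecutive global
#' tiers and are never highly expressed; highly expressed genes reach the
#' high threshold in one to three regions; pan-region genes reach it in
#' every region; silent genes stay below the detection threshold in every
#' sample; background genes are detected everywhere and never high.
#'
#' @param spec an [atlas_spec()].
#' @return list with \code{atlas} (an [expression_atlas()]) and
#'   \code{truth} (data.frame gene, class).
#' @export
generate_atlas <- function(spec = atlas_spec()) {
  if (!inherits(spec, "atlas_spec")) stop_bt("spec must be an atlas_spec")
  with_seed(spec$seed, {
    n_bg <- spec$n_genes - spec$n_housekeeping - spec$n_high -
      spec$n_silent - spec$n_pan_region_high
    mk <- function(prefix, n) if (n > 0) sprintf("%s%03d", prefix, seq_len(n)) else character(0)
    classes <- c(rep("housekeeping", spec$n_housekeeping),
                 rep("high", spec$n_high),
                 rep("pan_region_high", spec$n_pan_region_high),
                 rep("silent", spec$n_silent),
                 rep("background", n_bg))
    genes <- c(mk("HK", spec$n_housekeeping), mk("HIGH", spec$n_high),
               mk("PAN", spec$n_pan_region_high), mk("SIL", spec$n_silent),
               mk("BG", n_bg))
    profiles <- lapply(seq_along(genes), function(i) {
      p <- list(gene = genes[i], class = classes[i])
      if (classes[i] == "high")
        p$high_regions <- sample(spec$regions,
                                 sample(seq_len(min(3, length(spec$regions))), 1))
      if (classes[i] == "pan_region_high") p$high_regions <- spec$regions
      p
    })
    atlas <- simulate_profiles(profiles, spec$regions, spec$ages,
                               noise_sd = spec$noise_sd,
                               six_month_dip = spec$six_month_dip)
    list(atlas = atlas,
         truth = data.frame(gene = genes, class = classes,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic annotation map with planted enrichment
#'
#' Background terms annotate genes uniformly at \code{base_rate}; enriched
#' terms annotate genes of their target truth class at
#' \code{min(1, base_rate * fold)} and all other genes at the base rate.
#' Terms are guaranteed non-empty.
#'
#' @param genes gene identifiers of the universe.
#' @param n_terms number of background (null) terms.
#' @param enriched list of lists with \code{term}, \code{fold} (> 1) and
#'   \code{target_class}; may be empty.
#' @param truth data.frame (gene, class) as from [generate_atlas()];
#'   required when \code{enriched} is non-empty.
#' @param base_rate per-gene annotation probability.
#' @param seed RNG seed.
#' @return list with \code{annotations} (an [annotation_map()]) and
#'   \code{truth} (data.frame term, enriched, fold).
#' @export
generate_annotations <- function(genes, n_terms = 20, enriched = list(),
                                 truth = NULL, base_rate = 0.05, seed = 1) {
  if (n_terms < 1 && length(enriched) == 0) stop_bt("no terms requested")
  genes <- normalize_genes(genes)
  for (e in enriched) {
    if (is.null(e$term) || is.null(e$fold) || is.null(e$target_class))
      stop_bt("each enriched entry needs term, fold and target_class")
    if (e$fold <= 1) stop_bt("enriched fold must exceed 1")
    if (is.null(truth) || !e$target_class %in% truth$class)
      stop_bt("unknown target_class: %s", e$target_class %||% "?")
  }
  with_seed(seed, {
    draw <- function(p_vec) {
      repeat {
        hit <- stats::runif(length(genes)) < p_vec
        if (any(hit)) return(genes[hit])
      }
    }
    terms <- list()
    for (i in seq_len(n_terms))
      terms[[sprintf("T_NULL%03d", i)]] <- draw(rep(base_rate, length(genes)))
    truth_rows <- data.frame(term = names(terms),
                             enriched = FALSE, fold = 1,
                             stringsAsFactors = FALSE)
    for (e in enriched) {
      in_class <- genes %in% truth$gene[truth$class == e$target_class]
      p_vec <- ifelse(in_class, pmin(1, base_rate * e$fold), base_rate)
      terms[[e$term]] <- draw(p_vec)
      truth_rows <- rbind(truth_rows,
                          data.frame(term = e$term, enriched = TRUE,
                                     fold = e$fold, stringsAsFactors = FALSE))
    }
    list(annotations = annotation_map(terms), truth = truth_rows)
  })
}

#' Generate a synthetic interactome with planted hubs and module cores
#'
#' Random background edges among unplanted genes, plus optional planted hub
#' stars (a hub gene wired to a fixed number of partners) and a planted
#' module structure: each module receives internal chain edges; every core
#' module is wired to every other module with \code{inter_core_edges}
#' edges; peripheral modules receive no direct edges to each other.
#'
#' @param genes gene identifiers.
#' @param n_edges number of background edges to draw.
#' @param hubs named integer vector gene -> planted degree.
#' @param modules optional named list of gene vectors (disjoint).
#' @param cores names of \code{modules} acting as cores.
#' @param inter_core_edges edges planted per (core, other-module) pair.
#' @param seed RNG seed.
#' @return list with \code{net} (an [interactome()]) and \code{truth}
#'   (list: hubs, modules, cores).
#' @export
generate_interactome <- function(genes, n_edges = 0, hubs = NULL,
                                 modules = NULL, cores = NULL,
                                 inter_core_edges = 2, seed = 1) {
  genes <- normalize_genes(genes)
  if (!is.null(hubs)) {
    if (any(hubs >= length(genes)))
      stop_bt("planted hub degree must be below the number of genes")
    names(hubs) <- normalize_genes(names(hubs))
  }
  mod_genes <- unique(unlist(modules))
  if (length(mod_genes) != length(unlist(modules)))
    stop_bt("planted modules must be disjoint")
  with_seed(seed, {
    free <- setdiff(genes, mod_genes)
    e <- data.frame(a = character(0), b = character(0),
                    stringsAsFactors = FALSE)
    if (n_edges > 0) {
      if (length(free) < 2) stop_bt("not enough unplanted genes for background edges")
      a <- sample(free, n_edges * 2, replace = TRUE)
      b <- sample(free, n_edges * 2, replace = TRUE)
      ok <- a != b
      e <- rbind(e, data.frame(a = a[ok], b = b[ok],
                               stringsAsFactors = FALSE)[seq_len(min(n_edges, sum(ok))), ])
    }
    for (h in names(hubs)) {
      partners <- sample(setdiff(genes, h), hubs[[h]])
      e <- rbind(e, data.frame(a = h, b = partners, stringsAsFactors = FALSE))
    }
    if (!is.null(modules)) {
      for (m in modules) {
        if (length(m) > 1)
          e <- rbind(e, data.frame(a = m[-length(m)], b = m[-1],
                                   stringsAsFactors = FALSE))
      }
      for (cid in cores) {
        for (oid in setdiff(names(modules), cid)) {
          e <- rbind(e, data.frame(
            a = sample(modules[[cid]], inter_core_edges, replace = TRUE),
            b = sample(modules[[oid]], inter_core_edges, replace = TRUE),
            stringsAsFactors = FALSE))
        }
      }
    }
    if (nrow(e) == 0) stop_bt("generated interactome has no edges")
    list(net = interactome(e),
         truth = list(hubs = hubs, modules = modules, cores = cores))
  })
}

#' Generate a synthetic ordinal staining table
#'
#' Builds records whose [specificity_call()] under default thresholds
#' equals the supplied truth: glial genes stain moderate/strong in glia and
#' negative in neurons, neuronal genes the reverse, none all-negative,
#' mixed weak-to-strong on both sides. Cerebellar layers are random (they
#' do not enter the default call).
#'
#' @param genes gene identifiers.
#' @param class_map named character vector gene -> truth in
#'   \code{neuronal}/\code{glial}/\code{mixed}/\code{none}.
#' @param seed RNG seed.
#' @return a \code{staining_table} data.frame.
#' @export
generate_staining <- function(genes, class_map, seed = 1) {
  genes <- normalize_genes(genes)
  names(class_map) <- normalize_genes(names(class_map))
  bad <- setdiff(unique(class_map), c("neuronal", "glial", "mixed", "none"))
  if (length(bad) > 0) stop_bt("unknown truth class(es): %s", paste(bad, collapse = ", "))
  miss <- setdiff(genes, names(class_map))
  if (length(miss) > 0) stop_bt("class_map missing gene(s): %s", paste(miss, collapse = ", "))
  with_seed(seed, {
    rows <- lapply(genes, function(g) {
      cl <- class_map[[g]]
      neuron <- switch(cl,
        neuronal = c(sample(2:3, 1), sample(0:3, 2, replace = TRUE)),
        glial = c(0L, 0L, 0L),
        none = c(0L, 0L, 0L),
        mixed = sample(1:3, 3, replace = TRUE))
      glia <- switch(cl,
        neuronal = c(0L, 0L, 0L),
        glial = sample(2:3, 3, replace = TRUE),
        none = c(0L, 0L, 0L),
        mixed = sample(1:3, 3, replace = TRUE))
      cb <- if (cl == "none") c(0L, 0L, 0L) else sample(0:3, 3, replace = TRUE)
      c(neuron, glia, cb)
    })
    m <- do.call(rbind, rows)
    out <- data.frame(gene = genes, m, stringsAsFactors = FALSE)
    names(out) <- c("gene", neuron_sites, glia_sites, cb_sites)
    class(out) <- c("staining_table", "data.frame")
    out
  })
}
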