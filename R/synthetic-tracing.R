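#' Specification for a synthetic traced-cell table
#'
#' Parameterizes [gen_traced_cells()]: where rabies-labeled input cells land
#' (region, layer, hemisphere) and how many starter cells the injection site
#' holds.  All probability vectors must sum to 1.
#'
#' @param region_probs named numeric vector: probability that an input cell
#'   falls in each brain region.
#' @param layer_probs named list (by region) of named layer probability
#'   vectors; regions not listed use layer `"none"` (subcortical).
#' @param ipsi_fraction named numeric vector (by region) giving the
#'   probability that a cell is ipsilateral; regions not listed default to 1.
#' @param n_inputs number of input cells (mCherry+ GFP-).
#' @param n_starters number of starter cells (mCherry+ GFP+), placed in the
#'   local region.
#' @param starter_layer_probs named layer probability vector for starters.
#' @param local_region region label of the injection site (default "VISp").
#' @return Object of class `traced_cell_spec`.
#' @export
traced_cell_spec <- function(region_probs,
                             layer_probs = list(),
                             ipsi_fraction = numeric(0),
                             n_inputs = 1000, n_starters = 30,
                             starter_layer_probs = c("L1" = 0.1, "L2/3" = 0.4,
                                                     "L4" = 0.2, "L5" = 0.2,
                                                     "L6" = 0.1),
                             local_region = "VISp") {
  if (length(region_probs) == 0 || is.null(names(region_probs)))
    stop("invalid argument: `region_probs` must be a non-empty named vector",
         call. = FALSE)
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("probabilities in %s must be nonnegative and sum to 1", what),
           call. = FALSE)
  }
  check_probs(region_probs, "region_probs")
  for (rg in names(layer_probs)) check_probs(layer_probs[[rg]],
                                             paste0("layer_probs$", rg))
  check_probs(starter_layer_probs, "starter_layer_probs")
  if (any(ipsi_fraction < 0 | ipsi_fraction > 1))
    stop("`ipsi_fraction` entries must be in [0, 1]", call. = FALSE)
  structure(list(region_probs = region_probs, layer_probs = layer_probs,
                 ipsi_fraction = ipsi_fraction, n_inputs = n_inputs,
                 n_starters = n_starters,
                 starter_layer_probs = starter_layer_probs,
                 local_region = local_region),
            class = "traced_cell_spec")
}

#' Default traced-cell specification
#'
#' A brain-wide input distribution of the kind retrograde tracing from V1
#' interneurons produces: local V1 inputs dominate, followed by higher-order
#' visual areas, contralateral V1, retrosplenial and motor/cingulate cortex,
#' visual thalamus and small neuromodulatory contributions.  Values are
#' synthetic round numbers, not measurements.
#'
#' @param n_inputs,n_starters cell counts.
#' @return A [traced_cell_spec()].
#' @export
default_tracing_spec <- function(n_inputs = 1000, n_starters = 30) {
  layers_v1 <- c("L1" = 0.05, "L2/3" = 0.40, "L4" = 0.20, "L5" = 0.25,
                 "L6" = 0.10)
  traced_cell_spec(
    region_probs = c(VISp = 0.45, HVAs = 0.18, RSP = 0.08, MOs = 0.07,
                     SSp = 0.05, AUD = 0.04, LGd = 0.06, LP = 0.04,
                     TEa = 0.02, PAL = 0.01),
    layer_probs = list(
      VISp = layers_v1,
      HVAs = c("L2/3" = 0.4, "L4" = 0.1, "L5" = 0.35, "L6" = 0.15),
      RSP = c("L2/3" = 0.3, "L5" = 0.5, "L6" = 0.2),
      MOs = c("L2/3" = 0.3, "L5" = 0.5, "L6" = 0.2),
      SSp = c("L2/3" = 0.4, "L5" = 0.4, "L6" = 0.2),
      AUD = c("L2/3" = 0.4, "L5" = 0.4, "L6" = 0.2),
      TEa = c("L2/3" = 0.3, "L5" = 0.5, "L6" = 0.2)),
    ipsi_fraction = c(VISp = 0.92, HVAs = 0.85, RSP = 0.95, MOs = 0.9,
                      SSp = 0.95, AUD = 0.9, LGd = 1, LP = 1, TEa = 0.9,
                      PAL = 1),
    n_inputs = n_inputs, n_starters = n_starters)
}

#' Generate a synthetic traced-cell table
#'
#' Samples `n_inputs` presynaptic input cells (mCherry+ GFP-) multinomially
#' across regions, layers and hemispheres per the spec, plus `n_starters`
#' starter cells (mCherry+ GFP+) in the local region with the starter layer
#' distribution.
#'
#' @param spec a [traced_cell_spec()].
#' @param seed RNG seed.
#' @return data.frame with columns `cell_id`, `region`, `hemisphere`
#'   (`ipsi`/`contra`), `layer` (`L1`,`L2/3`,`L4`,`L5`,`L6`,`none`), `gfp`,
#'   `mcherry`.
#' @export
gen_traced_cells <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "traced_cell_spec"))
  with_seed(seed, {
    regions <- sample(names(spec$region_probs), spec$n_inputs, replace = TRUE,
                      prob = spec$region_probs)
    layer <- vapply(regions, function(rg) {
      lp <- spec$layer_probs[[rg]]
      if (is.null(lp)) "none" else sample(names(lp), 1, prob = lp)
    }, character(1))
    ipsi_p <- vapply(regions, function(rg) {
      p <- spec$ipsi_fraction[rg]
      if (is.na(p)) 1 else unname(p)
    }, numeric(1))
    hemi <- ifelse(runif(spec$n_inputs) < ipsi_p, "ipsi", "contra")
    inputs <- data.frame(region = regions, hemisphere = hemi, layer = layer,
                         gfp = 0L, mcherry = 1L, stringsAsFactors = FALSE)
    starters <- if (spec$n_starters > 0) {
      data.frame(region = spec$local_region, hemisphere = "ipsi",
                 layer = sample(names(spec$starter_layer_probs),
                                spec$n_starters, replace = TRUE,
                                prob = spec$starter_layer_probs),
                 gfp = 1L, mcherry = 1L, stringsAsFactors = FALSE)
    } else NULL
    out <- rbind(inputs, starters)
    out <- cbind(cell_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}
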