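# Parameterisation of the full interfacial structure: the shared under-layers
# (Si | SiO2/permalloy mix | permalloy | gold | COOH-OEG-SAM) and the floating
# protein-lipid membrane (solution interlayer | optional inner protein |
# inner heads | tails | outer heads | peripheral protein), rendered as slab
# stacks, SLD profiles and component volume-fraction profiles.

#' Under-layer structure
#'
#' The layers between the silicon substrate and the gold/water interface,
#' shared across every dataset of an experiment: a mixed silicon
#' dioxide/permalloy layer adjacent to the substrate, a permalloy layer, a
#' gold layer, and the carboxyl-terminated oligoethyleneglycol self-assembled
#' monolayer (COOH-OEG-SAM). Each layer's `*_roughness` is the Gaussian width
#' of its top (solution-side) interface; `si_roughness` is the
#' substrate/oxide interface. The SAM layer is `sam_coverage` SAM and
#' `1 - sam_coverage` solvent.
#'
#' All lengths in Angstrom, fractions in `[0, 1]`.
#'
#' @param si_roughness,mix_thickness,mix_permalloy,mix_roughness,permalloy_thickness,permalloy_roughness,gold_thickness,gold_roughness,sam_thickness,sam_coverage,sam_roughness
#'   Structural parameters (see description).
#' @return An object of class `nr_underlayers` (named list).
#' @export
underlayers <- function(si_roughness = 3,
                        mix_thickness = 12, mix_permalloy = 0.5,
                        mix_roughness = 4,
                        permalloy_thickness = 120, permalloy_roughness = 5,
                        gold_thickness = 90, gold_roughness = 4,
                        sam_thickness = 25, sam_coverage = 0.92,
                        sam_roughness = 9) {
  u <- as.list(environment())
  validate_fractions(u["mix_permalloy"], u["sam_coverage"])
  validate_nonneg(u[grep("thickness|roughness", names(u))])
  structure(u, class = "nr_underlayers")
}

#' Floating membrane structure
#'
#' The multilayer added above the SAM when a floating protein-lipid membrane
#' is present: a pure-solvent interlayer, an optional inner protein
#' distribution (protein and water only), an inner headgroup region (lipid
#' headgroups, protein, water), a lipid tail region (tails, protein, water),
#' an outer headgroup region, and an extra-membranous peripheral protein
#' distribution facing the bulk solution. Per layer, lipid + protein
#' fractions must not exceed 1; solvent fills the remainder.
#'
#' A single `bilayer_roughness` applies to all membrane-internal interfaces
#' (interlayer top through outer-heads top); the peripheral layer's outer
#' interface carries its own `peripheral_roughness`. By default the outer
#' headgroup layer mirrors the inner one (`symmetric_heads = TRUE`); set the
#' `outer_head_*` arguments for an asymmetric membrane.
#'
#' @param interlayer_thickness Solution interlayer between SAM and membrane
#'   (Angstrom); this is the membrane-to-SAM distance.
#' @param inner_protein_thickness,inner_protein_fraction Optional inner
#'   protein layer (thickness 0 removes it).
#' @param head_thickness,head_lipid,head_protein Inner headgroup layer.
#' @param tail_thickness,tail_lipid,tail_protein Lipid tail layer.
#' @param outer_head_thickness,outer_head_lipid,outer_head_protein Outer
#'   headgroup layer; `NA` (default) mirrors the inner values.
#' @param peripheral_thickness,peripheral_protein,peripheral_roughness
#'   Extra-membranous protein layer and its outer roughness.
#' @param bilayer_roughness Common roughness of membrane-internal interfaces.
#' @param symmetric_heads Keep outer heads locked to inner heads.
#' @return An object of class `nr_membrane` (named list).
#' @export
floating_membrane <- function(interlayer_thickness = 11,
                              inner_protein_thickness = 0,
                              inner_protein_fraction = 0,
                              head_thickness = 8, head_lipid = 0.42,
                              head_protein = 0.24,
                              tail_thickness = 30, tail_lipid = 0.61,
                              tail_protein = 0.24,
                              outer_head_thickness = NA,
                              outer_head_lipid = NA, outer_head_protein = NA,
                              peripheral_thickness = 50.5,
                              peripheral_protein = 0.13,
                              peripheral_roughness = 16.5,
                              bilayer_roughness = 7,
                              symmetric_heads = TRUE) {
  m <- as.list(environment())
  structure(m, class = "nr_membrane")
}

validate_fractions <- function(...) {
  v <- unlist(list(...))
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad)) {
    stop("fractions out of [0, 1]: ", paste(names(v)[bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(v)
}

validate_nonneg <- function(x) {
  v <- unlist(x)
  bad <- !is.na(v) & v < 0
  if (any(bad)) {
    stop("must be >= 0: ", paste(names(v)[bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(v)
}

# Resolve the (possibly mirrored) outer headgroup values.
outer_heads_of <- function(m) {
  if (isTRUE(m$symmetric_heads) || is.na(m$outer_head_thickness)) {
    list(thickness = m$head_thickness, lipid = m$head_lipid,
         protein = m$head_protein)
  } else {
    list(thickness = m$outer_head_thickness,
         lipid = m$outer_head_lipid %||% m$head_lipid,
         protein = m$outer_head_protein %||% m$head_protein)
  }
}

COMPONENTS <- c("si", "sio2", "permalloy", "gold", "sam",
                "lipid_heads", "lipid_tails", "protein")

# Internal layer description: one entry per finite layer (fronting Si and
# backing solvent excluded) with thickness, top-interface roughness and the
# volume fraction of each non-solvent component. The bottom roughness of the
# first layer is the substrate roughness. Built from plain vectors (this is
# the innermost hot path of every objective evaluation).
layer_table <- function(under, membrane = NULL) {
  stopifnot(inherits(under, "nr_underlayers"))
  nm <- list(); th <- list(); ro <- list(); cp <- list()
  add <- function(layer, thickness, roughness, ...) {
    dots <- c(...)
    if (sum(dots) > 1 + 1e-9) {
      stop("layer '", layer, "' composition sums to ", signif(sum(dots), 6),
           " > 1", call. = FALSE)
    }
    comp <- numeric(length(COMPONENTS))
    comp[match(names(dots), COMPONENTS)] <- dots
    k <- length(nm) + 1
    nm[[k]] <<- layer; th[[k]] <<- thickness; ro[[k]] <<- roughness
    cp[[k]] <<- comp
  }
  add("sio2_permalloy_mix", under$mix_thickness, under$mix_roughness,
      sio2 = 1 - under$mix_permalloy, permalloy = under$mix_permalloy)
  add("permalloy", under$permalloy_thickness, under$permalloy_roughness,
      permalloy = 1)
  add("gold", under$gold_thickness, under$gold_roughness, gold = 1)
  add("sam", under$sam_thickness, under$sam_roughness,
      sam = under$sam_coverage)
  if (!is.null(membrane)) {
    stopifnot(inherits(membrane, "nr_membrane"))
    m <- membrane
    oh <- outer_heads_of(m)
    add("interlayer", m$interlayer_thickness, m$bilayer_roughness)
    if (m$inner_protein_thickness > 0) {
      add("inner_protein", m$inner_protein_thickness, m$bilayer_roughness,
          protein = m$inner_protein_fraction)
    }
    add("inner_heads", m$head_thickness, m$bilayer_roughness,
        lipid_heads = m$head_lipid, protein = m$head_protein)
    add("tails", m$tail_thickness, m$bilayer_roughness,
        lipid_tails = m$tail_lipid, protein = m$tail_protein)
    add("outer_heads", oh$thickness, m$bilayer_roughness,
        lipid_heads = oh$lipid, protein = oh$protein)
    add("peripheral_protein", m$peripheral_thickness,
        m$peripheral_roughness, protein = m$peripheral_protein)
  }
  thickness <- unlist(th)
  roughness <- unlist(ro)
  if (any(thickness < 0) || any(roughness < 0)) {
    stop("negative thickness or roughness in layer table", call. = FALSE)
  }
  comp <- do.call(rbind, cp)
  colnames(comp) <- COMPONENTS
  list(layer = unlist(nm), thickness = thickness, roughness = roughness,
       comp = comp, si_roughness = under$si_roughness)
}

# Endpoint SLD matrix for the standard components (rows = COMPONENTS), used
# to evaluate all slab SLDs at a contrast with one matrix product.
component_endpoints <- function(materials) {
  i <- match(COMPONENTS, materials$material)
  if (anyNA(i)) {
    stop("materials table must contain: ",
         paste(COMPONENTS[is.na(i)], collapse = ", "), call. = FALSE)
  }
  cbind(h2o = materials$sld_h2o[i], d2o = materials$sld_d2o[i])
}

# Slab vectors (no tibble) for the hot path.
render_slabs_fast <- function(lt, f, ep) {
  slds <- ep[, "h2o"] + f * (ep[, "d2o"] - ep[, "h2o"])
  sld <- as.numeric(lt$comp %*% slds) +
    (1 - rowSums(lt$comp)) * water_sld(f)
  list(
    thickness = c(0, lt$thickness, 0),
    sld = c(slds[COMPONENTS == "si"][1], sld, water_sld(f)),
    roughness = c(lt$si_roughness, lt$roughness, 0)
  )
}

#' Render the interfacial model as a slab stack
#'
#' Produces the ordered slab list (fronting silicon | under-layers |
#' optional membrane layers | backing solvent) with each slab's SLD computed
#' from its component volume fractions at the requested solvent contrast via
#' [layer_sld()]. The beam enters through the silicon substrate (inverted
#' solid-liquid geometry).
#'
#' @param under An [underlayers()] object.
#' @param membrane A [floating_membrane()] object, or `NULL` for the bare
#'   surface measured before membrane deposition.
#' @param contrast Contrast name or D2O fraction (see [material_sld()]).
#' @param materials,contrasts Lookup tables.
#' @return A slab tibble (see [slab_stack()]) with a `layer` column.
#' @export
render_slabs <- function(under, membrane = NULL, contrast,
                         materials = default_materials(),
                         contrasts = standard_contrasts()) {
  lt <- layer_table(under, membrane)
  f <- resolve_d2o_fraction(contrast, contrasts)
  s <- render_slabs_fast(lt, f, component_endpoints(materials))
  tibble(
    layer = c("si", lt$layer, "solvent"),
    thickness = s$thickness,
    sld = s$sld,
    roughness = s$roughness
  )
}

#' Component volume-fraction profile
#'
#' Builds each component's depth profile as a sum of erf-edged boxcar
#' functions on a regular z grid (z = 0 at the silicon surface, increasing
#' toward bulk solution; default 1 Angstrom spacing). Adjacent layers share
#' interfaces exactly, so occupancy telescopes; water is reported as the
#' unoccupied volume, making the fractions sum to 1 at every grid point.
#' The profile is contrast-independent.
#'
#' @inheritParams render_slabs
#' @param dz Grid spacing in Angstrom.
#' @return A tibble of class `nr_profile` with column `z` and one column per
#'   component (`si`, `sio2`, `permalloy`, `gold`, `sam`, `lipid_heads`,
#'   `lipid_tails`, `protein`, `water`).
#' @export
component_profile <- function(under, membrane = NULL, dz = 1) {
  lt <- layer_table(under, membrane)
  n <- length(lt$layer)
  z_if <- cumsum(c(0, lt$thickness))                   # n+1 interfaces
  sig <- pmax(c(lt$si_roughness, lt$roughness), 1e-6)
  z_lo <- -4 * sig[1] - dz
  z_hi <- z_if[n + 1] + 4 * sig[n + 1] + dz
  z <- seq(floor(z_lo), ceiling(z_hi), by = dz)
  # cumulative edge functions Phi_i(z), one per interface
  edges <- vapply(seq_len(n + 1),
                  function(i) pnorm((z - z_if[i]) / sig[i]),
                  numeric(length(z)))
  prof <- matrix(0, length(z), length(COMPONENTS),
                 dimnames = list(NULL, COMPONENTS))
  prof[, "si"] <- 1 - edges[, 1]
  for (i in seq_len(n)) {
    box <- edges[, i] - edges[, i + 1]
    comp <- lt$comp[i, ]
    for (cn in COMPONENTS[comp > 0]) {
      prof[, cn] <- prof[, cn] + comp[[cn]] * box
    }
  }
  water <- 1 - rowSums(prof)
  out <- tibble::as_tibble(cbind(tibble(z = z), prof, tibble(water = water)))
  class(out) <- c("nr_profile", class(out))
  out
}

#' Scattering-length-density depth profile
#'
#' \eqn{\rho(z) = \sum_c \phi_c(z)\,\rho_c + \phi_w(z)\,\rho_w}: the
#' component volume-fraction profile contracted with the per-component SLDs
#' at the given contrast. This is exactly the profile that the microslicing
#' reflectivity path discretises.
#'
#' @inheritParams render_slabs
#' @inheritParams component_profile
#' @return A tibble with columns `z` (Angstrom) and `sld`
#'   (\eqn{10^{-6} \AA^{-2}}).
#' @export
sld_profile <- function(under, membrane = NULL, contrast, dz = 1,
                        materials = default_materials(),
                        contrasts = standard_contrasts()) {
  f <- resolve_d2o_fraction(contrast, contrasts)
  prof <- component_profile(under, membrane, dz = dz)
  slds <- material_sld(COMPONENTS, f, materials, contrasts)
  sld <- as.matrix(prof[, COMPONENTS]) %*% slds + prof$water * water_sld(f)
  tibble(z = prof$z, sld = as.numeric(sld))
}

#' Membrane-to-SAM distance
#'
#' The thickness of the pure-solvent interlayer separating the SAM's top
#' edge from the inner headgroups — the headline "membrane-to-SAM distance"
#' tuned by the solution salt conditions.
#'
#' @param membrane A [floating_membrane()] object.
#' @return Distance in Angstrom.
#' @export
membrane_to_sam_distance <- function(membrane) {
  if (is.null(membrane) || !inherits(membrane, "nr_membrane")) {
    stop("membrane-to-SAM distance is undefined for a bare surface",
         call. = FALSE)
  }
  membrane$interlayer_thickness
}

#' Export a volume-fraction profile as tab-separated text
#'
#' Writes the z grid and component columns with a unit-bearing header.
#'
#' @param profile An `nr_profile` tibble from [component_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# component volume fraction profile",
    "# z in Angstrom (0 at the Si surface, increasing toward solution);",
    "# remaining columns are volume fractions (sum to 1)"
  ), con)
  utils::write.table(profile, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
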