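#' Dendritic morphology as a rooted branch tree
#'
#' A `morph_tree` holds the dendritic arbour as a set of tapered-cylinder
#' branches (radius and length per branch, parent links) plus the soma
#' cylinder dimensions.  It is the input to the equivalent-cylinder
#' collapse.
#'
#' @param branches data.frame with columns `id`, `parent_id` (NA or -1 for
#'   branches attached to the soma/root), `radius_um`, `length_um`.
#' @param soma list with `length_um` and `diameter_um` (default the
#'   published 22 x 22 um cylinder).
#' @return An object of class `morph_tree`.
#' @export
morph_tree <- function(branches,
                       soma = list(length_um = 22, diameter_um = 22)) {
  need <- c("id", "parent_id", "radius_um", "length_um")
  if (!all(need %in% names(branches)))
    stop("branches must have columns ", paste(need, collapse = ", "))
  branches <- as.data.frame(branches)[need]
  if (nrow(branches) < 1) stop("tree has no dendritic branches to collapse")
  if (anyDuplicated(branches$id)) stop("branch ids must be unique")
  if (any(branches$radius_um <= 0)) stop("branch radii must be positive")
  if (any(branches$length_um <= 0)) stop("branch lengths must be positive")
  root <- is.na(branches$parent_id) | branches$parent_id < 0
  if (sum(root) < 1) stop("tree must have at least one root branch")
  if (any(!root & !(branches$parent_id %in% branches$id)))
    stop("parent_id refers to a missing branch")
  # acyclicity: walk each branch to the root
  idx <- match(branches$parent_id, branches$id)
  for (i in seq_len(nrow(branches))) {
    seen <- integer(0); j <- i
    while (!root[j]) {
      if (j %in% seen) stop("parent links contain a cycle")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  structure(list(branches = branches, soma = soma), class = "morph_tree")
}

#' @export
print.morph_tree <- function(x, ...) {
  cat(sprintf("morph_tree: %d dendritic branch(es), soma %.4g x %.4g um\n",
              nrow(x$branches), x$soma$length_um, x$soma$diameter_um))
  invisible(x)
}

#' Equivalent cylinder
#'
#' A cylinder described by radius and length, with derived volume and
#' lateral (side-wall, no end caps) surface area.
#'
#' @param radius_um,length_um cylinder dimensions (um).
#' @return Object of class `equiv_cylinder` with fields `radius_um`,
#'   `length_um`, `volume_um3`, `lateral_area_um2`.
#' @export
equiv_cylinder <- function(radius_um, length_um) {
  if (radius_um <= 0 || length_um <= 0)
    stop("cylinder radius and length must be positive")
  structure(list(radius_um = radius_um, length_um = length_um,
                 volume_um3 = pi * radius_um^2 * length_um,
                 lateral_area_um2 = 2 * pi * radius_um * length_um),
            class = "equiv_cylinder")
}

#' @export
print.equiv_cylinder <- function(x, ...) {
  cat(sprintf(
    "equivalent cylinder: L = %.4g um, R = %.4g um (D = %.4g um)\n",
    x$length_um, x$radius_um, 2 * x$radius_um))
  cat(sprintf("  volume = %.6g um3, lateral area = %.6g um2\n",
              x$volume_um3, x$lateral_area_um2))
  invisible(x)
}

#' Collapse a dendritic arbour into one equivalent cylinder
#'
#' Merges all dendritic branches into a single cylinder that conserves
#' axial resistance: the radius is the root-sum-square of the branch radii,
#' R = sqrt(sum r_i^2), and the length is the radius-weighted average of
#' the branch lengths, l = sum(l_i r_i) / sum(r_i).
#'
#' @param tree a [morph_tree()].
#' @return An [equiv_cylinder()].
#' @examples
#' tr <- morph_tree(data.frame(id = 1:2, parent_id = c(NA, 1),
#'                             radius_um = c(1, 1), length_um = c(100, 200)))
#' collapse_tree(tr)  # R = sqrt(2), l = 150
#' @export
collapse_tree <- function(tree) {
  stopifnot(inherits(tree, "morph_tree"))
  b <- tree$branches
  if (nrow(b) < 1) stop("tree has no dendritic branches to collapse")
  R <- sqrt(sum(b$radius_um^2))
  l <- sum(b$length_um * b$radius_um) / sum(b$radius_um)
  equiv_cylinder(R, l)
}

#' Re-length a cylinder at constant volume
#'
#' Sets the cylinder length to `new_length_um` and adjusts the radius to
#' R = sqrt(V / (pi l)) so that the volume is unchanged.  Used to restore
#' electrotonic separation between soma and dendrite after the collapse,
#' which shortens the arbour.
#'
#' @param cyl an [equiv_cylinder()].
#' @param new_length_um target length (um), must be positive.
#' @return A new [equiv_cylinder()] of equal volume.
#' @export
relength_cylinder <- function(cyl, new_length_um) {
  stopifnot(inherits(cyl, "equiv_cylinder"))
  if (!is.finite(new_length_um) || new_length_um <= 0)
    stop("new_length_um must be positive")
  R <- sqrt(cyl$volume_um3 / (pi * new_length_um))
  equiv_cylinder(R, new_length_um)
}

#' Dendritic correction factor
#'
#' Ratio of the total membrane surface area of the original dendritic
#' segments to the surface area of their equivalent cylinder.  Conductance
#' densities, membrane capacitance and the Ca2+ shell depth of the
#' collapsed dendrite are multiplied by this factor to compensate for the
#' membrane area lost in the collapse.  Both areas may be supplied
#' externally (e.g. measured by a reconstruction tool); no recomputation is
#' forced.
#'
#' @param full_area_um2 total dendritic membrane area of the arbour (um2).
#' @param cylinder_area_um2 lateral area of the equivalent cylinder (um2).
#' @return The dimensionless ratio, at full precision.
#' @examples
#' compute_cd(42310, 6874)  # ~6.16
#' @export
compute_cd <- function(full_area_um2, cylinder_area_um2) {
  if (!is.finite(full_area_um2) || full_area_um2 <= 0 ||
      !is.finite(cylinder_area_um2) || cylinder_area_um2 <= 0)
    stop("areas must be positive")
  full_area_um2 / cylinder_area_um2
}

#' Apply the dendritic correction factor to a parameter table
#'
#' Multiplies every dendritic maximal density, membrane capacitance and
#' Ca2+ shell depth entry by `cd`; somatic entries are left untouched (the
#' soma does not enter the collapse).
#'
#' @param tbl data.frame with columns `parameter`, `compartment`
#'   (`"soma"` or `"dendrite"`) and `value`.
#' @param cd correction factor, must be positive.
#' @return The table with dendritic values scaled.
#' @export
apply_cd <- function(tbl, cd) {
  need <- c("parameter", "compartment", "value")
  if (!all(need %in% names(tbl)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (!is.finite(cd) || cd <= 0) stop("cd must be positive")
  dend <- tbl$compartment == "dendrite"
  tbl$value[dend] <- tbl$value[dend] * cd
  tbl
}

#' Full reduction pipeline: collapse, re-length, correction factor
#'
#' Collapses the arbour, optionally re-lengths the equivalent cylinder at
#' constant volume, and computes the dendritic correction factor from the
#' arbour's total lateral membrane area and the (re-lengthed) cylinder's
#' lateral area.  Changing `target_length_um` automatically updates the
#' radius (volume conservation) and the correction factor, so the dendrite
#' length is the single tuning knob.
#'
#' @param tree a [morph_tree()].
#' @param target_length_um optional new cylinder length (um).
#' @param full_area_um2 optional externally measured arbour area (um2);
#'   defaults to the sum of lateral branch areas of `tree`.
#' @return List of class `reduction_result`: `cylinder`
#'   (an [equiv_cylinder()]), `collapsed` (pre-re-length cylinder), `cd`,
#'   `full_dendrite_area_um2`.
#' @export
reduce_morphology <- function(tree, target_length_um = NULL,
                              full_area_um2 = NULL) {
  collapsed <- collapse_tree(tree)
  cyl <- if (is.null(target_length_um)) collapsed
         else relength_cylinder(collapsed, target_length_um)
  if (is.null(full_area_um2)) {
    b <- tree$branches
    full_area_um2 <- sum(2 * pi * b$radius_um * b$length_um)
  }
  cd <- compute_cd(full_area_um2, cyl$lateral_area_um2)
  structure(list(cylinder = cyl, collapsed = collapsed, cd = cd,
                 full_dendrite_area_um2 = full_area_um2),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("Dendritic reduction\n")
  cat(sprintf("  collapsed: L = %.4g um, D = %.4g um\n",
              x$collapsed$length_um, 2 * x$collapsed$radius_um))
  if (!identical(x$collapsed, x$cylinder))
    cat(sprintf("  re-lengthed: L = %.4g um, R = %.4g um (volume kept)\n",
                x$cylinder$length_um, x$cylinder$radius_um))
  cat(sprintf("  arbour area = %.6g um2, cylinder area = %.6g um2\n",
              x$full_dendrite_area_um2, x$cylinder$lateral_area_um2))
  cat(sprintf("  C_d = %.4g\n", x$cd))
  invisible(x)
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), 1-based ids,
#' radii in um.  Soma samples (type 1) define the soma; dendritic samples
#' (types 3 and 4) become branches whose length is the euclidean distance
#' to the parent sample and whose radius is the sample radius.  Samples of
#' other types (axon etc.) are ignored.
#'
#' @param path SWC file path.
#' @return A [morph_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("SWC file has no sample records: ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 7) stop("SWC records must have 7 columns")
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  sw <- as.data.frame(m)

  soma_s <- sw[sw$type == 1, , drop = FALSE]
  soma <- if (nrow(soma_s)) {
    # soma approximated as a cylinder with length = diameter = 2 max radius
    d <- 2 * max(soma_s$radius)
    list(length_um = d, diameter_um = d)
  } else list(length_um = 22, diameter_um = 22)

  dend <- sw[sw$type %in% c(3, 4), , drop = FALSE]
  if (!nrow(dend)) stop("SWC file contains no dendritic samples (type 3/4)")
  par_idx <- match(dend$parent, sw$id)
  if (anyNA(par_idx) && any(dend$parent != -1))
    stop("SWC parent pointer refers to a missing sample")
  len <- sqrt((dend$x - sw$x[par_idx])^2 + (dend$y - sw$y[par_idx])^2 +
              (dend$z - sw$z[par_idx])^2)
  len[dend$parent == -1 | is.na(len)] <- NA
  keep <- !is.na(len) & len > 0
  dend <- dend[keep, , drop = FALSE]
  len <- len[keep]
  # a parent that is a soma sample (or absent from the dendrite set) roots
  # the branch
  parent_id <- ifelse(dend$parent %in% dend$id, dend$parent, NA)
  morph_tree(data.frame(id = dend$id, parent_id = parent_id,
                        radius_um = dend$radius, length_um = len),
             soma = soma)
}

#' Write a morphology tree as SWC
#'
#' Serializes a [morph_tree()] back to standard 7-column SWC: one soma root
#' sample (type 1) plus one sample per branch (type 3), laid out along the
#' x axis so that inter-sample distances reproduce the branch lengths.
#'
#' @param tree a [morph_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "morph_tree"))
  b <- tree$branches
  n <- nrow(b)
  id_map <- setNames(seq_len(n) + 1L, b$id)   # soma sample takes id 1
  root <- is.na(b$parent_id) | b$parent_id < 0
  # x position: cumulative length from the root along the parent chain
  xpos <- numeric(n)
  idx <- match(b$parent_id, b$id)
  for (i in seq_len(n)) {
    x <- 0; j <- i
    repeat {
      x <- x + b$length_um[j]
      if (root[j]) break
      j <- idx[j]
    }
    xpos[i] <- x
  }
  lines <- c(
    "# generated by purkinje2c::write_swc",
    sprintf("1 1 0 0 0 %.9g -1", tree$soma$diameter_um / 2),
    sprintf("%d 3 %.9g %.9g 0 %.9g %d",
            id_map[as.character(b$id)], xpos,
            # y offset separates sibling branches without changing lengths
            rep(0, n), b$radius_um,
            ifelse(root, 1L, id_map[as.character(b$parent_id)])))
  writeLines(lines, path)
  invisible(path)
}

#' Axial coupling resistance between soma and dendrite centres
#'
#' R = Ra (L_s/2) / (pi r_s^2) + Ra (L_d/2) / (pi r_d^2): half of each
#' cylinder's axial resistance, in series.
#'
#' @param soma_length_um,soma_radius_um soma dimensions (um).
#' @param dend_length_um,dend_radius_um dendrite dimensions (um).
#' @param ra_ohm_cm specific axial resistivity (Ohm cm).
#' @return Resistance in MOhm.
#' @export
axial_resistance <- function(soma_length_um, soma_radius_um,
                             dend_length_um, dend_radius_um,
                             ra_ohm_cm = 35.4) {
  ra_um <- ra_ohm_cm * 1e4                       # Ohm um
  r_ohm <- ra_um * (soma_length_um / 2) / (pi * soma_radius_um^2) +
           ra_um * (dend_length_um / 2) / (pi * dend_radius_um^2)
  r_ohm / 1e6
}

#' Write a plain-text reduction report
#'
#' @param res a `reduction_result` from [reduce_morphology()].
#' @param path output file path.
#' @param cd_table optional parameter table (see [apply_cd()]) to append in
#'   scaled form.
#' @return `path`, invisibly.
#' @export
write_reduction_report <- function(res, path, cd_table = NULL) {
  stopifnot(inherits(res, "reduction_result"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# dendritic reduction report (lengths um, areas um2, volumes um3)",
    sprintf("collapsed_length,%.10g", res$collapsed$length_um),
    sprintf("collapsed_radius,%.10g", res$collapsed$radius_um),
    sprintf("cylinder_length,%.10g", res$cylinder$length_um),
    sprintf("cylinder_radius,%.10g", res$cylinder$radius_um),
    sprintf("cylinder_volume,%.10g", res$cylinder$volume_um3),
    sprintf("cylinder_area,%.10g", res$cylinder$lateral_area_um2),
    sprintf("full_dendrite_area,%.10g", res$full_dendrite_area_um2),
    sprintf("cd,%.10g", res$cd)), con)
  if (!is.null(cd_table)) {
    scaled <- apply_cd(cd_table, res$cd)
    writeLines("# scaled parameter table", con)
    writeLines(sprintf("%s,%s,%.10g", scaled$parameter, scaled$compartment,
                       scaled$value), con)
  }
  invisible(path)
}
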