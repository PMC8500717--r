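#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that checks the coordinates are
#' finite and keeps the source path as the structure id.
#'
#' @param path Path to a PDB file.
#' @return A `bio3d` `pdb` object.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ", path)
  pdb$call <- path
  pdb
}

.atom_xyz <- function(pdb, resno, elety, chain = NULL) {
  sel <- pdb$atom$resno == resno & pdb$atom$elety == elety
  if (!is.null(chain)) sel <- sel & pdb$atom$chain == chain
  i <- which(sel)
  if (length(i) == 0) return(NULL)
  as.numeric(pdb$atom[i[1], c("x", "y", "z")])
}

#' Beta-carbon distance between two residues
#'
#' Euclidean distance between the CB atoms of two sites, the standard
#' structure-derived reference for probe-pair separations. Glycine lacks a
#' CB; its CA is used instead, with a warning.
#'
#' @param pdb A `pdb` object from [read_structure()].
#' @param site_a,site_b Residue numbers.
#' @param chain Optional chain identifier.
#' @return Distance (A).
#' @export
beta_carbon_distance <- function(pdb, site_a, site_b, chain = NULL) {
  get_cb <- function(site) {
    xyz <- .atom_xyz(pdb, site, "CB", chain)
    if (is.null(xyz)) {
      xyz <- .atom_xyz(pdb, site, "CA", chain)
      if (is.null(xyz)) stop("residue ", site, " has no CB or CA atom")
      warning("residue ", site, " has no CB (glycine?); using CA")
    }
    xyz
  }
  sqrt(sum((get_cb(site_a) - get_cb(site_b))^2))
}

# ---- internal geometry -----------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Natural-extension (NeRF) atom placement: new atom D bonded to C with the
# given bond length, angle B-C-D and torsion A-B-C-D (degrees).
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d
}

# Probe templates: each atom is (name, anchors, bond A, angle deg, torsion).
# torsion is either a number (rigid) or "chiK" (sampled). Coarse idealized
# heavy-atom placements; the reference atom carries the FRET-relevant point
# (acridone carbonyl carbon, or the Cu2+ ion).
.probe_template <- function(kind) {
  switch(kind,
    acd = list(
      atoms = list(
        list("CG", c("N", "CA", "CB"), 1.50, 112, "chi1"),
        list("A1", c("CA", "CB", "CG"), 1.40, 120, "chi2"),
        list("A2", c("CB", "CG", "A1"), 1.40, 120, 180),
        list("A3", c("CG", "A1", "A2"), 1.40, 120, 0),
        list("A4", c("A1", "A2", "A3"), 1.40, 120, 180),
        list("A5", c("A2", "A3", "A4"), 1.40, 120, 0),
        list("A6", c("A3", "A4", "A5"), 1.40, 120, 180)),
      reference = "A4", n_torsions = 2),
    cu_tetac = list(
      atoms = list(
        list("SG", c("N", "CA", "CB"), 1.81, 114, "chi1"),
        list("SD", c("CA", "CB", "SG"), 2.05, 104, "chi2"),
        list("C1", c("CB", "SG", "SD"), 1.81, 104, "chi3"),
        list("C2", c("SG", "SD", "C1"), 1.52, 112, "chi4"),
        list("NC", c("SD", "C1", "C2"), 1.47, 112, "chi5"),
        list("CU", c("C1", "C2", "NC"), 2.10, 109, 180),
        list("RA", c("C2", "NC", "CU"), 2.10, 90, 0),
        list("RB", c("C2", "NC", "CU"), 2.10, 90, 180)),
      reference = "CU", n_torsions = 5),
    cu_dihis = list(
      atoms = list(
        list("CG", c("N", "CA", "CB"), 1.50, 114, "chi1"),
        list("ND1", c("CA", "CB", "CG"), 1.38, 122, "chi2"),
        list("CD2", c("CA", "CB", "CG"), 1.36, 122, "chi2+180"),
        list("CE1", c("CB", "CG", "ND1"), 1.32, 109, 180),
        list("NE2", c("CG", "ND1", "CE1"), 1.35, 108, 0),
        list("CU", c("ND1", "CE1", "NE2"), 2.03, 127, 180)),
      reference = "CU", n_torsions = 2),
    cb = list(atoms = list(), reference = "CB", n_torsions = 0),
    stop("unknown probe kind '", kind, "'")
  )
}

# Ideal CB when the structure lacks one (e.g. glycine host site).
.ideal_cb <- function(n, ca, c) .place_atom(c, n, ca, 1.53, 110.4, 122.5)

.build_probe <- function(template, anchors, chis) {
  coords <- anchors
  for (at in template$atoms) {
    tor <- at[[5]]
    if (is.character(tor)) {
      if (grepl("\\+180$", tor)) {
        k <- as.integer(sub("chi(\\d+)\\+180", "\\1", tor))
        tor <- chis[k] + 180
      } else {
        tor <- chis[as.integer(sub("chi", "", tor))]
      }
    }
    a <- coords[[at[[2]][1]]]; b <- coords[[at[[2]][2]]]; c <- coords[[at[[2]][3]]]
    coords[[at[[1]]]] <- as.numeric(.place_atom(a, b, c, at[[3]], at[[4]], tor))
  }
  coords
}

#' Sample a rotamer cloud of a probe grafted at a site
#'
#' Random torsion sampling of a simplified idealized probe template grafted
#' onto the backbone of one residue, with hard-sphere clash rejection against
#' the protein's heavy atoms (the host residue's own sidechain, which the
#' probe replaces, is ignored; hydrogens are absent from crystal structures
#' and not modeled). Under the `"tight"` policy a conformer is rejected if
#' any probe atom comes within 3.4 A of a protein atom; `"loose"` uses a
#' 2.5 A cutoff and tolerates up to 5 contacts.
#'
#' For `probe = "cu_dihis"` supply `partner_site` (the i +/- 4 companion
#' histidine): rotamers are sampled at both residues under the loose policy
#' and only pairs whose Cu positions agree to within `pair_cutoff` are kept,
#' mimicking a Cu2+ ion shared by the two imidazoles; the retained reference
#' point is the midpoint of each qualifying Cu pair.
#'
#' @param pdb A `pdb` object.
#' @param site Residue number of the labeled site.
#' @param probe `"acd"`, `"cu_tetac"`, `"cu_dihis"`, or `"cb"` (no probe:
#'   single conformer at the beta carbon).
#' @param policy Van der Waals policy, `"tight"` (3.4 A, 0 clashes) or
#'   `"loose"` (2.5 A, up to 5 clashes). `cu_dihis` defaults to loose.
#' @param n_rotamers Number of accepted conformers to aim for (<= 200).
#' @param max_attempts Attempt budget before declaring the site buried.
#' @param seed RNG seed; sampling is reproducible for a fixed seed.
#' @param chain Optional chain identifier.
#' @param partner_site Companion residue for `cu_dihis`.
#' @param pair_cutoff Maximum Cu-Cu distance (A) for a di-histidine pair.
#' @return An object of class `rotamer_cloud`: list with `site`, `probe`,
#'   `points` (n x 3 matrix of reference-point coordinates), `count`, and
#'   `acceptance_rate`.
#' @export
sample_rotamers <- function(pdb, site, probe = c("acd", "cu_tetac", "cu_dihis", "cb"),
                            policy = NULL, n_rotamers = 200,
                            max_attempts = 10000, seed = 42, chain = NULL,
                            partner_site = NULL, pair_cutoff = 1.0) {
  probe <- match.arg(probe)
  if (n_rotamers > 200) stop("at most 200 rotamers per site")
  if (is.null(policy)) policy <- if (probe == "cu_dihis") "loose" else "tight"
  policy <- match.arg(policy, c("tight", "loose"))

  if (probe == "cu_dihis") {
    if (is.null(partner_site)) stop("cu_dihis requires a partner_site (i +/- 4)")
    a <- .sample_site(pdb, site, "cu_dihis", policy, n_rotamers, max_attempts,
                      seed, chain, exclude_extra = partner_site)
    b <- .sample_site(pdb, partner_site, "cu_dihis", policy, n_rotamers,
                      max_attempts, seed + 1, chain, exclude_extra = site)
    dd <- .pairwise_dist(a$points, b$points)
    keep <- which(dd <= pair_cutoff, arr.ind = TRUE)
    if (nrow(keep) == 0)
      stop("no di-histidine rotamer pairs share a Cu2+ site within ",
           pair_cutoff, " A")
    pts <- (a$points[keep[, 1], , drop = FALSE] +
              b$points[keep[, 2], , drop = FALSE]) / 2
    if (nrow(pts) > n_rotamers) pts <- pts[seq_len(n_rotamers), , drop = FALSE]
    return(structure(list(site = site, probe = probe, points = pts,
                          count = nrow(pts),
                          acceptance_rate = min(a$acceptance_rate,
                                                b$acceptance_rate)),
                     class = "rotamer_cloud"))
  }
  .sample_site(pdb, site, probe, policy, n_rotamers, max_attempts, seed, chain)
}

.pairwise_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

.sample_site <- function(pdb, site, probe, policy, n_rotamers, max_attempts,
                         seed, chain, exclude_extra = NULL) {
  template <- .probe_template(probe)
  cutoff <- if (policy == "tight") 3.4 else 2.5
  max_clashes <- if (policy == "tight") 0 else 5

  n <- .atom_xyz(pdb, site, "N", chain)
  ca <- .atom_xyz(pdb, site, "CA", chain)
  cc <- .atom_xyz(pdb, site, "C", chain)
  if (is.null(n) || is.null(ca) || is.null(cc))
    stop("site ", site, " lacks backbone atoms N/CA/C")
  cb <- .atom_xyz(pdb, site, "CB", chain)
  if (is.null(cb)) cb <- as.numeric(.ideal_cb(n, ca, cc))
  anchors <- list(N = n, CA = ca, C = cc, CB = cb)

  if (template$n_torsions == 0) {
    return(structure(list(site = site, probe = probe,
                          points = matrix(anchors[[template$reference]], 1, 3),
                          count = 1L, acceptance_rate = 1),
                     class = "rotamer_cloud"))
  }

  # protein heavy atoms, excluding the host residue (its sidechain is being
  # replaced) and hydrogens
  atm <- pdb$atom
  keep <- atm$resno != site & !grepl("^H", atm$elety)
  if (!is.null(exclude_extra))
    keep <- keep & !(atm$resno %in% exclude_extra &
                       !atm$elety %in% c("N", "CA", "C", "O", "CB"))
  if (!is.null(chain)) keep <- keep | atm$chain != chain
  env <- as.matrix(atm[keep, c("x", "y", "z")])

  old <- .Random.seed_save()
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  attempts <- 0L
  while (nrow(pts) < n_rotamers && attempts < max_attempts) {
    attempts <- attempts + 1L
    chis <- stats::runif(template$n_torsions, -180, 180)
    coords <- .build_probe(template, anchors, chis)
    probe_xyz <- do.call(rbind, coords[vapply(template$atoms, `[[`, "", 1)])
    if (nrow(env) > 0) {
      d <- .pairwise_dist(probe_xyz, env)
      if (sum(d < cutoff) > max_clashes) next
    }
    pts <- rbind(pts, coords[[template$reference]])
  }
  .Random.seed_restore(old)
  if (nrow(pts) == 0)
    stop("site ", site, " appears buried: no clash-free rotamer in ",
         max_attempts, " attempts")
  structure(list(site = site, probe = probe, points = pts,
                 count = nrow(pts), acceptance_rate = nrow(pts) / attempts),
            class = "rotamer_cloud")
}

#' Pairwise distance distribution between two rotamer clouds
#'
#' All-pairs distances between the reference points of two clouds, binned
#' into a histogram normalized to unit area, plus the distance between the
#' cloud centroids (the single-number distance prediction comparable to a
#' fitted mean distance).
#'
#' @param cloud_a,cloud_b [sample_rotamers()] results.
#' @param bin_width Histogram bin width (A).
#' @return A list with `histogram` (data frame `r_angstrom`, `density`),
#'   `centroid_distance`, `mean_distance`, and the distance `range`.
#' @export
cloud_distance_distribution <- function(cloud_a, cloud_b, bin_width = 0.5) {
  stopifnot(inherits(cloud_a, "rotamer_cloud"), inherits(cloud_b, "rotamer_cloud"))
  d <- as.numeric(.pairwise_dist(cloud_a$points, cloud_b$points))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  h <- graphics::hist(d, breaks = seq(lo, hi, by = bin_width), plot = FALSE)
  ca <- colMeans(cloud_a$points)
  cb <- colMeans(cloud_b$points)
  list(histogram = data.frame(r_angstrom = h$mids, density = h$density),
       centroid_distance = sqrt(sum((ca - cb)^2)),
       mean_distance = mean(d), range = range(d))
}
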