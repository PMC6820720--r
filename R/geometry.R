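#' r^-6 effective distance between two methyl groups
#'
#' Aggregates the nine inter-proton distances between two rotating methyl
#' groups into a single effective distance
#' \deqn{d_{eff} = \left(\sum_{i=1}^3\sum_{j=1}^3 d_{ij}^{-6}\right)^{-1/6},}
#' the quantity against which the NOE distance cutoff is applied. When all
#' nine distances are (approximately) equal to \eqn{d}, this reduces to
#' \eqn{9^{-1/6} d \approx 0.693\,d}.
#'
#' @param d numeric vector or matrix of the nine pairwise proton-proton
#'   distances in Angstrom. `Inf` entries are allowed (they contribute
#'   nothing to the sum); zero or negative distances are an error.
#' @return effective distance in Angstrom (scalar).
#' @examples
#' noe_effective_distance(rep(4, 9)) # 9^(-1/6) * 4
#' @export
noe_effective_distance <- function(d) {
  d <- as.numeric(d)
  if (length(d) != 9L) {
    stop("expected the 9 inter-proton distances of a methyl pair, got ",
         length(d))
  }
  if (any(d <= 0)) stop("coincident or invalid proton positions (d <= 0)")
  sum(d^-6)^(-1 / 6)
}

#' @rdname noe_effective_distance
#' @param a,b either 3x3 matrices of methyl proton coordinates (rows = the
#'   three protons, columns = x/y/z in Angstrom) or single rows of a methyl
#'   table as returned by [extract_methyl_groups()].
#' @export
effective_distance <- function(a, b) {
  pa <- methyl_protons(a)
  pb <- methyl_protons(b)
  d <- proton_cross_distances(pa, pb)
  noe_effective_distance(d)
}

methyl_protons <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 3L, ncol(x) == 3L)
    return(x)
  }
  if (is.data.frame(x) && "protons" %in% names(x)) {
    if (nrow(x) != 1L) stop("expected a single methyl group")
    return(x$protons[[1L]])
  }
  stop("cannot interpret methyl proton coordinates")
}

proton_cross_distances <- function(pa, pb) {
  # 3x3 matrix of |pa_i - pb_j|
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  dz <- outer(pa[, 3], pb[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Largest inter-carbon separation admitted by an effective-distance cutoff
#'
#' Under the equal-distance approximation (all nine proton-proton distances
#' equal), a cutoff `d_cut` on the effective distance admits proton-proton
#' distances up to \eqn{9^{1/6} d_{cut}} and therefore carbon-carbon
#' separations up to \eqn{9^{1/6} d_{cut} + 2 \times 1.1} Angstrom,
#' accounting for the two C-H bonds.
#'
#' @param d_cut effective-distance cutoff in Angstrom.
#' @param bond C-H bond length in Angstrom (1.1 by default).
#' @return maximal carbon-carbon separation in Angstrom.
#' @examples
#' max_carbon_separation(5) # about 9.4 Angstrom
#' @export
max_carbon_separation <- function(d_cut, bond = 1.1) {
  d_cut * 9^(1 / 6) + 2 * bond
}

#' Ideal methyl proton construction
#'
#' Places the three protons of a methyl group with idealized tetrahedral
#' geometry: C-H bond length 1.1 Angstrom, H-C-stem angle 109.47 degrees,
#' and the protons staggered (torsion angles 60, 180 and 300 degrees) with
#' respect to a reference substituent on the stem atom. Used when the input
#' structure carries no hydrogen atoms; hydrogens present in the input are
#' used verbatim and this construction is skipped.
#'
#' @param carbon methyl carbon position (numeric xyz, Angstrom).
#' @param stem the single heavy atom bonded to the methyl carbon.
#' @param ref a heavy atom bonded to the stem, defining the torsion origin.
#' @param bond C-H bond length (Angstrom).
#' @return 3x3 matrix of proton coordinates (rows = protons).
#' @export
build_methyl_protons <- function(carbon, stem, ref, bond = 1.1) {
  carbon <- as.numeric(carbon); stem <- as.numeric(stem); ref <- as.numeric(ref)
  u <- carbon - stem
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) stop("degenerate geometry: carbon and stem coincide")
  u <- u / nu
  v <- ref - stem
  v_perp <- v - sum(v * u) * u
  nv <- sqrt(sum(v_perp^2))
  if (nv < 1e-8) stop("degenerate geometry: stem-reference direction collinear with bond")
  e1 <- v_perp / nv
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  theta <- (180 - 109.47) * pi / 180 # angle between C->H and the stem->C axis
  tau <- c(60, 180, 300) * pi / 180
  h <- vapply(tau, function(t) {
    dirn <- cos(theta) * u + sin(theta) * (cos(t) * e1 + sin(t) * e2)
    carbon + bond * dirn
  }, numeric(3))
  t(h)
}
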