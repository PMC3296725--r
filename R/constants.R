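#' Physical and geometric constants
#'
#' Constants used throughout the package.  All energies are in kcal/mol,
#' distances in Angstrom, temperatures in Kelvin and rate constants in
#' min^-1.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R}{gas constant, 1.9872e-3 kcal mol^-1 K^-1}
#'   \item{T_ref}{reference temperature for intrinsic exchange rates, 293 K}
#'   \item{disulfide_cutoff}{maximum S-S distance of a cystine bridge, 2.3 A}
#'   \item{hbond_cutoff}{maximum donor-N to acceptor-O distance, 3.28 A}
#'   \item{contact_cutoff}{backbone-N contact-order cutoff, 7.0 A}
#'   \item{tolerance}{default free-energy comparison tolerance, 0.4 kcal/mol}
#'   \item{bond}{standard backbone bond lengths used by the fixture
#'     builders (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 A)}
#'   \item{angle}{standard backbone bond angles in degrees
#'     (N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8)}
#' }
#' @export
cf_constants <- list(
  R = 1.9872e-3,
  T_ref = 293,
  disulfide_cutoff = 2.3,
  hbond_cutoff = 3.28,
  contact_cutoff = 7.0,
  tolerance = 0.4,
  bond = c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231),
  angle = c(n_ca_c = 111.0, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.8)
)
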