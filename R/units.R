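# Unit conventions: positions are stored internally in bohr; exchange files
# carry coordinates in Angstrom. Multipoles are atomic units throughout
# (e, e*bohr, e*bohr^2). Potentials are hartree/e internally.

#' Physical constants used by the package
#'
#' @format A named list with elements
#'   \describe{
#'     \item{bohr_to_angstrom}{CODATA value 0.529177210903 \eqn{\mathrm{\AA}}/bohr.}
#'     \item{hartree_to_kcal}{627.5094740631 kcal/mol per hartree, used to
#'       report electrostatic potentials in kcal mol^-1 e^-1.}
#'   }
#' @export
qdr_constants <- list(
  bohr_to_angstrom = 0.529177210903,
  hartree_to_kcal  = 627.5094740631
)

ang_to_bohr <- function(x) x / qdr_constants$bohr_to_angstrom
bohr_to_ang <- function(x) x * qdr_constants$bohr_to_angstrom

# pair weight entering every resorption block
op_weight <- function(op) 2 * tanh(2 * op)
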