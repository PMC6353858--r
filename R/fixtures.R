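# Worked-example fixtures: the five-reaction example network, a balanced
# flux map, tracer and fragment specifications, and a deterministic fixture
# generator for file-based workflows.

#' Text of the five-reaction example network model
#'
#' The classic EMU illustration network: a linear A to F backbone with a
#' reversible isomerization, a cleavage and a condensation.
#'
#' @return character vector of reaction lines in the \code{\link{parseModel}}
#'   grammar
#' @export
exampleModelText <- function() c(
    "1: A (abc) -> B (abc)",
    "2: B (abc) <-> D (abc)",
    "3: B (abc) -> C (bc) + E (a)",
    "4: B (abc) + C (de) -> D (bcd) + E (a) + E (e)",
    "5: D (abc) -> F (abc)")

#' The example network model
#'
#' @return a \linkS4class{NetworkModel} with input A and outputs E, F
#' @export
exampleModel <- function() parseModel(exampleModelText())

#' A balanced flux map for the example network
#'
#' Constructed by solving the stoichiometric steady state with the input
#' flux normalized to 100 and the two remaining degrees of freedom — the
#' cleavage/condensation branch flux and the backward (exchange) flux of the
#' reversible isomerization — fixed at the given values.
#'
#' @param branch flux through the cleavage/condensation branch (default 20)
#' @param exchange backward flux of the reversible reaction (default 50)
#' @return named unidirectional flux map passing \code{\link{checkBalance}}
#' @export
exampleFluxes <- function(branch = 20, exchange = 50)
    balancedFluxes(exampleModel(),
                   fix = c("1" = 100, "4" = branch, "2_b" = exchange))

#' The TBDMS-derivatized aspartate 418 > 244 fragment
#'
#' Parent fragment m/z 418 (C18H40O4NSi3) containing all four aspartate
#' carbons; daughter fragment m/z 244 (C10H22O2NSi2) containing C1 and C2.
#'
#' @return a \linkS4class{FragmentSpec}
#' @export
aspartateFragment <- function()
    fragmentSpec("ASP", "C18H40O4NSi3", "C10H22O2NSi2",
                 coreAtoms = 1:4, daughterCore = 1:2)

#' Worked-example tracer specifications
#'
#' \itemize{
#'   \item \code{A2}: [2-13C]A at 100\% purity, pure 12C background — the
#'     didactic setting for the example network simulations.
#'   \item \code{A23}: [2,3-13C] labeling of a four-carbon metabolite.
#'   \item \code{ASP14}: [1,4-13C]aspartate at 99\% isotopic purity.
#' }
#'
#' @return named list of \linkS4class{TracerSpec} objects
#' @export
exampleTracers <- function() list(
    A2 = tracerSpec(3, positions = 2, purity = 1, background = "pure"),
    A23 = tracerSpec(4, positions = c(2, 3), purity = 1, background = "pure"),
    ASP14 = tracerSpec(4, positions = c(1, 4), purity = 0.99, background = "pure"))

writeTracerYAML <- function(tracer, path) {
    pos <- which(tracer@labeled)
    y <- list(n_atoms = tracer@nAtoms,
              positions = lapply(pos, function(p)
                  list(position = p, purity = tracer@purity[p])),
              background = tracer@background)
    yaml::write_yaml(y, path)
    invisible(path)
}

writeFragmentYAML <- function(frag, path) {
    y <- list(metabolite = frag@metabolite,
              parent_formula = formulaToString(frag@parentFormula),
              daughter_formula = formulaToString(frag@daughterFormula),
              core_atoms = as.list(frag@coreAtoms),
              daughter_core = as.list(frag@daughterCore))
    yaml::write_yaml(y, path)
    invisible(path)
}

#' Generate the packaged worked-example fixtures
#'
#' Writes the example model, its balanced flux map, tracer and fragment
#' specifications, and the default isotope table to \code{outDir}, plus a
#' \code{manifest.json} with MD5 content hashes. Idempotent: reruns produce
#' byte-identical files.
#'
#' @param outDir writable output directory (created if needed)
#' @return invisibly, the manifest as a named list of file MD5 hashes
#' @export
generateFixtures <- function(outDir) {
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
        stop(sprintf("cannot create fixture directory '%s'", outDir))
    writeLines(exampleModelText(), file.path(outDir, "model.txt"))
    writeFluxMap(exampleFluxes(), file.path(outDir, "fluxes.csv"))
    tr <- exampleTracers()
    writeTracerYAML(tr$A2, file.path(outDir, "tracer_2-13C_A.yaml"))
    writeTracerYAML(tr$A23, file.path(outDir, "tracer_23-13C_A.yaml"))
    writeTracerYAML(tr$ASP14, file.path(outDir, "tracer_14-13C_ASP.yaml"))
    writeFragmentYAML(aspartateFragment(),
                      file.path(outDir, "fragment_ASP_418_244.yaml"))
    file.copy(system.file("extdata", "isotopes.csv", package = "tandemEMU",
                          mustWork = TRUE),
              file.path(outDir, "isotopes.csv"), overwrite = TRUE)
    files <- c("model.txt", "fluxes.csv", "tracer_2-13C_A.yaml",
               "tracer_23-13C_A.yaml", "tracer_14-13C_ASP.yaml",
               "fragment_ASP_418_244.yaml", "isotopes.csv")
    manifest <- as.list(tools::md5sum(file.path(outDir, files)))
    names(manifest) <- files
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
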