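# MM/GBSA bookkeeping.
#
# Gas-phase MM terms and the GB polar solvation term are consumed from
# per-frame tables computed upstream; this module only combines them:
#   dG_binding = dE_MM + dG_sol - TdS
#   dE_MM      = dE_int + dE_ele + dE_vdw
#   dG_sol     = dG_pol + dG_nonpol
#   dG_nonpol  = gamma * dSASA + b
# The entropy term is recorded but defaults to 0 (neglected).

.eq3_cols <- c("dE_int", "dE_ele", "dE_vdw", "dG_pol")

#' Read a per-frame energy-term table
#'
#' Delimited text, one row per frame.  Required columns: `frame`, `dE_int`,
#' `dE_ele`, `dE_vdw`, `dG_pol` (all kcal/mol, complex - receptor - ligand
#' differences).  Optional: `dG_nonpol`, or the SASA triple `sasa_complex`,
#' `sasa_receptor`, `sasa_ligand` (A^2) from which it is derived; per-residue
#' decomposition columns named `res_<label>` (e.g. `res_G14`, `res_MG`).
#'
#' @param path file path (tab- or comma-delimited; sniffed from the header).
#' @return data.frame.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl(",", hdr)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(tab$frame)) stop("duplicate frame indices in ", path)
  tab
}

#' Nonpolar solvation term from a SASA difference
#'
#' `gamma * dSASA + b`.
#'
#' @param dsasa SASA difference (complex - receptor - ligand), A^2.
#' @param gamma surface-tension coefficient, kcal/(mol A^2) (default 0.0072).
#' @param b offset, kcal/mol (default 0).
#' @return kcal/mol.
#' @export
nonpolar_term <- function(dsasa, gamma = 0.0072, b = 0) {
  gamma * dsasa + b
}

.frame_nonpolar <- function(tab, gamma, b) {
  if ("dG_nonpol" %in% names(tab)) return(tab$dG_nonpol)
  sc <- c("sasa_complex", "sasa_receptor", "sasa_ligand")
  if (all(sc %in% names(tab))) {
    return(nonpolar_term(tab$sasa_complex - tab$sasa_receptor -
                           tab$sasa_ligand, gamma, b))
  }
  stop("missing column: dG_nonpol (or the sasa_complex/receptor/ligand triple)")
}

.window_rows <- function(tab, window) {
  nf <- nrow(tab)
  keep <- ceiling(window * nf)
  if (window <= 0 || window > 1 || keep == 0L || nf == 0L) {
    stop("empty analysis window")
  }
  tab[seq.int(nf - keep + 1L, nf), , drop = FALSE]
}

#' Combine per-frame energy terms into a binding free energy
#'
#' Per frame, dG = (dE_int + dE_ele + dE_vdw) + (dG_pol + dG_nonpol) - TdS.
#' The reported total is the mean of the per-replicate window means; the SD
#' is taken across replicate means (set `pooled_sd = TRUE` for the SD over
#' all pooled window frames instead).
#'
#' @param tables one energy table (data.frame) or a list of them, one per
#'   replicate.
#' @param window trailing window fraction in (0, 1] (default 0.6).
#' @param entropy the -TdS term, kcal/mol (default 0: entropy neglected).
#' @param gamma,b nonpolar-term coefficients (used only when `dG_nonpol` must
#'   be derived from SASA columns).
#' @param pooled_sd logical; SD over pooled frames instead of across
#'   replicate means.
#' @return list of class `"bfe_result"`: `total`, `sd`, `components` (means
#'   of dE_int, dE_ele, dE_vdw, dG_pol, dG_nonpol, dE_MM, dG_sol),
#'   `entropy`, `replicate_means`.
#' @export
bfe_combine <- function(tables, window = 0.6, entropy = 0,
                        gamma = 0.0072, b = 0, pooled_sd = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  per_frame <- lapply(tables, function(tab) {
    miss <- setdiff(.eq3_cols, names(tab))
    if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
    tab <- .window_rows(tab, window)
    np <- .frame_nonpolar(tab, gamma, b)
    data.frame(dE_int = tab$dE_int, dE_ele = tab$dE_ele,
               dE_vdw = tab$dE_vdw, dG_pol = tab$dG_pol, dG_nonpol = np,
               dG = tab$dE_int + tab$dE_ele + tab$dE_vdw + tab$dG_pol + np +
                 entropy)
  })
  rmeans <- vapply(per_frame, function(d) mean(d$dG), numeric(1))
  comp <- colMeans(do.call(rbind, per_frame))
  components <- c(comp[.eq3_cols], dG_nonpol = unname(comp["dG_nonpol"]),
                  dE_MM = unname(sum(comp[c("dE_int", "dE_ele", "dE_vdw")])),
                  dG_sol = unname(comp["dG_pol"] + comp["dG_nonpol"]))
  sdv <- if (pooled_sd) {
    stats::sd(unlist(lapply(per_frame, `[[`, "dG")))
  } else if (length(rmeans) > 1L) stats::sd(rmeans) else 0
  structure(list(total = mean(rmeans), sd = sdv, components = components,
                 entropy = entropy, replicate_means = rmeans),
            class = "bfe_result")
}

#' @export
print.bfe_result <- function(x, ...) {
  cat(sprintf("<bfe_result> dG_binding = %.2f +/- %.2f kcal/mol (%d replicate(s))\n",
              x$total, x$sd, length(x$replicate_means)))
  invisible(x)
}

#' Per-residue binding free energy decomposition
#'
#' Window means of every `res_<label>` column per replicate, then mean and
#' SD across replicates.  Rows are sorted by residue number; a `res_MG`
#' column is reported as its own `MG` row (last).
#'
#' @param tables one energy table or a list of replicate tables; every table
#'   must carry the same `res_*` columns.
#' @param window trailing window fraction (default 0.6).
#' @return data.frame with `residue`, `mean`, `sd`.
#' @export
bfe_per_residue <- function(tables, window = 0.6) {
  if (is.data.frame(tables)) tables <- list(tables)
  cols <- grep("^res_", names(tables[[1]]), value = TRUE)
  if (!length(cols)) stop("no per-residue decomposition columns (res_*)")
  for (tab in tables) {
    if (!identical(grep("^res_", names(tab), value = TRUE), cols)) {
      stop("ragged decomposition columns across replicates")
    }
  }
  per <- vapply(tables, function(tab) {
    colMeans(.window_rows(tab, window)[, cols, drop = FALSE])
  }, numeric(length(cols)))
  per <- matrix(per, nrow = length(cols))
  lab <- sub("^res_", "", cols)
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", lab)))
  ord <- order(is.na(num), num)
  data.frame(residue = lab,
             mean = rowMeans(per),
             sd = if (ncol(per) > 1L) apply(per, 1, stats::sd) else 0,
             row.names = NULL)[ord, , drop = FALSE]
}

#' Absolute difference between two binding free energies
#'
#' @param a,b `bfe_result` objects or numeric totals, kcal/mol.
#' @return `|total(a) - total(b)|`, kcal/mol.
#' @export
bfe_difference <- function(a, b) {
  ta <- if (inherits(a, "bfe_result")) a$total else as.numeric(a)
  tb <- if (inherits(b, "bfe_result")) b$total else as.numeric(b)
  abs(ta - tb)
}
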