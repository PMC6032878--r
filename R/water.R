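#' Build the irrigation water budget
#'
#' Runoff is pooled per food production unit (FPU), non-agricultural
#' consumption and an environmental reserve are subtracted, and the
#' remaining water is allocated equally across the FPU's grid cells:
#' `available_fpu = max(0, runoff - non_ag - reserve_frac * runoff)`.
#'
#' @param cells data.frame (`cell_id`, `fpu_id`, `runoff_km3`).
#' @param fpus data.frame (`fpu_id`, `non_ag_km3`, `reserve_frac`).
#' @return list of class `water_budget`: `fpu` table with `runoff_km3`,
#'   `available_km3`; and vectors `cell_id`, `cell_available_km3`.
#' @examples
#' cells <- data.frame(cell_id = c("a", "b"), fpu_id = "f",
#'                     runoff_km3 = c(6, 6))
#' fpus <- data.frame(fpu_id = "f", non_ag_km3 = 2, reserve_frac = 0)
#' build_water_budget(cells, fpus)$cell_available_km3  # 5, 5
#' @export
build_water_budget <- function(cells, fpus) {
  stopifnot(all(c("cell_id", "fpu_id", "runoff_km3") %in% names(cells)),
            all(c("fpu_id", "non_ag_km3", "reserve_frac") %in% names(fpus)),
            all(cells$runoff_km3 >= 0), all(fpus$non_ag_km3 >= 0),
            all(fpus$reserve_frac >= 0 & fpus$reserve_frac <= 1))
  runoff_fpu <- tapply(cells$runoff_km3, cells$fpu_id, sum)
  n_cells <- tapply(cells$runoff_km3, cells$fpu_id, length)
  fpu <- fpus
  fpu$runoff_km3 <- as.numeric(runoff_fpu[fpu$fpu_id])
  fpu$runoff_km3[is.na(fpu$runoff_km3)] <- 0
  fpu$available_km3 <- pmax(0, fpu$runoff_km3 - fpu$non_ag_km3 -
                              fpu$reserve_frac * fpu$runoff_km3)
  per_cell <- fpu$available_km3 / pmax(as.numeric(n_cells[fpu$fpu_id]), 1)
  alloc <- per_cell[match(cells$fpu_id, fpu$fpu_id)]
  structure(list(fpu = fpu, cell_id = cells$cell_id,
                 cell_available_km3 = alloc),
            class = "water_budget")
}

#' Water budget of a synthetic world
#'
#' Convenience wrapper deriving non-agricultural consumption from the
#' world's per-FPU fraction of runoff.
#'
#' @param world an `agro_world`.
#' @return a `water_budget` (see [build_water_budget()]).
#' @export
world_water_budget <- function(world) {
  runoff_fpu <- tapply(world$cells$runoff_km3, world$cells$fpu_id, sum)
  fpus <- world$fpus
  fpus$non_ag_km3 <- fpus$non_ag_frac *
    as.numeric(runoff_fpu[fpus$fpu_id])
  build_water_budget(
    world$cells[, c("cell_id", "fpu_id", "runoff_km3")],
    fpus[, c("fpu_id", "non_ag_km3", "reserve_frac")])
}
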