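# ---------------------------------------------------------------------------
# File I/O: VTK image-data snapshots, checkpoints, CSV logs, JSON mesh
# summaries, and the reference configuration.
# ---------------------------------------------------------------------------

#' Write one block as a VTK image-data (.vti) file
#'
#' ASCII XML ImageData with the requested fields as cell data; the image
#' origin and spacing reflect the block's physical placement.
#'
#' @param h hierarchy (for domain bounds).
#' @param level a `tmg_level`.
#' @param block a `tmg_block` of that level.
#' @param path output file path.
#' @param fields field names to include (derived `phi_T`/`phi_H` are
#'   computed on the fly when requested).
#' @return `path`, invisibly.
#' @export
write_vti <- function(h, level, block, path, fields) {
  n <- block_dims(block)
  org <- h$domain$L + (block$lo - 1L) * level$eta
  con <- file(path, "w")
  on.exit(close(con))
  ext <- sprintf("0 %d 0 %d 0 %d", n[1], n[2], n[3])
  cat(sprintf('<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">\n'),
      sprintf('  <ImageData WholeExtent="%s" Origin="%g %g %g" Spacing="%g %g %g">\n',
              ext, org[1], org[2], org[3], level$eta, level$eta, level$eta),
      sprintf('    <Piece Extent="%s">\n', ext),
      '      <CellData>\n', sep = "", file = con)
  for (f in fields) {
    vals <- block_field_values(block, f)
    cat(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">\n', f),
        file = con)
    writeLines(paste(format(as.vector(vals), digits = 10,
                            scientific = TRUE), collapse = " "), con)
    cat('        </DataArray>\n', file = con)
  }
  cat('      </CellData>\n    </Piece>\n  </ImageData>\n</VTKFile>\n',
      file = con)
  invisible(path)
}

# interior values of a (possibly derived) field
block_field_values <- function(block, f) {
  if (f == "phi_T")
    return(interior(block$data$phi_V) + interior(block$data$phi_D))
  if (f == "phi_H")
    return(1 - interior(block$data$phi_V) - interior(block$data$phi_D) -
             interior(block$data$phi_E))
  interior(block$data[[f]])
}

#' Write snapshots, logs and the mesh summary of a state
#'
#' Emits one `.vti` file per block (every level), the residual/DOF log as
#' CSV, a JSON mesh summary, and a checkpoint.
#'
#' @param state a `tmg_state`.
#' @param out_dir output directory (created if missing).
#' @param fields fields to export (default: phases, potentials, pressure,
#'   oxygen, glucose, growth factors, vessels).
#' @return `out_dir`, invisibly.
#' @export
write_output <- function(state, out_dir,
                         fields = c("phi_V", "phi_D", "phi_E", "phi_T",
                                    "phi_H", "mu_T", "mu_E", "p", "n",
                                    "g", "tgf", "taf", "m", "F_E",
                                    "B_nE", "L_nE")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  h <- state$h
  tag <- sprintf("step%06d", state$step)
  for (kappa in h$kappa_min:h$kappa_max) {
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks)) {
      fl <- intersect(fields, c(names(lv$blocks[[ib]]$data),
                                "phi_T", "phi_H"))
      write_vti(h, lv, lv$blocks[[ib]],
                file.path(out_dir, sprintf("%s_L%+d_B%03d.vti", tag,
                                           kappa, ib)), fl)
    }
  }
  if (nrow(state$log) > 0L)
    utils::write.csv(state$log, file.path(out_dir, "log.csv"),
                     row.names = FALSE)
  mesh_summary(h, file.path(out_dir, sprintf("%s_mesh.json", tag)))
  write_checkpoint(state, file.path(out_dir, sprintf("%s.rds", tag)))
  invisible(out_dir)
}

#' Write / read a checkpoint
#'
#' Checkpoints use R's native serialization; the round-trip is lossless
#' (bit-identical arrays) and restarted runs reproduce direct runs exactly
#' -- the model is deterministic.
#'
#' @param state a `tmg_state`.
#' @param path file path.
#' @return `path` (write) or the restored state (read).
#' @export
write_checkpoint <- function(state, path) {
  saveRDS(state, path)
  path
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

#' Write the reference model configuration
#'
#' Emits every model parameter with its default and a provenance tag:
#' `"model"` for constants printed in the model description, `"placeholder"`
#' for supplementary-only constants shipped as documented defaults.
#'
#' @param params a [model_params()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_reference_config <- function(params = model_params(), path) {
  printed <- c("lambda_M_V", "lambda_N_V", "lambda_L_D", "lambda_F_E",
               "lambda_de_E", "F_n_EF", "n_h", "n_v_V", "g_v_V", "n_v_F",
               "tgf_F_E", "B_inf", "L_inf", "phi_V_seed", "phi_E0")
  out <- list()
  for (nm in setdiff(names(params), "Q3")) {
    out[[nm]] <- list(value = params[[nm]],
                      provenance = if (nm %in% printed) "model"
                      else "placeholder")
  }
  out$Q3 <- list(value = "smoothstep x^2(3-2x)", provenance = "placeholder")
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a model configuration written by [write_reference_config()]
#'
#' @param path YAML path.
#' @return a [model_params()] with the stored values.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- lapply(raw[setdiff(names(raw), "Q3")], function(e) {
    v <- e$value
    if (is.list(v)) unlist(v) else v
  })
  do.call(model_params, vals)
}
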