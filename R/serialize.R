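# Weight-level persistence of built networks: a JSON header describing the
# layer graph plus a little-endian float64 blob holding every parameter and
# batch-norm running statistic in a fixed traversal order.

layer_header_ <- function(ly) {
  meta <- ly[setdiff(names(ly), c("params", "state"))]
  list(meta = meta,
       params = lapply(ly$params, function(p) dim(p) %||% length(p)),
       state = lapply(ly$state, function(p) dim(p) %||% length(p)))
}

#' Save a network's structure and weights
#'
#' Writes `<prefix>.json` (layer graph and tensor shapes) and
#' `<prefix>.bin` (all weights and running statistics as little-endian
#' doubles), so a trained model can be reloaded bit-identically.
#'
#' @param net A `"locomode_net"`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_network <- function(net, prefix) {
  header <- list(
    name = net$name, n_classes = net$n_classes,
    input_shapes = net$input_shapes,
    heads = lapply(net$heads, function(h) lapply(h, layer_header_)),
    trunk = lapply(net$trunk, layer_header_))
  write_json_(header, paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (ly in c(unlist(unname(net$heads), recursive = FALSE), net$trunk)) {
    for (p in ly$params) writeBin(as.vector(p), con, size = 8L,
                                  endian = "little")
    for (p in ly$state) writeBin(as.vector(p), con, size = 8L,
                                 endian = "little")
  }
  invisible(prefix)
}

read_layer_ <- function(h, con) {
  ly <- h$meta
  # scalars arrive as length-1 lists from JSON
  for (nm in names(ly))
    if (is.list(ly[[nm]])) ly[[nm]] <- unlist(ly[[nm]])
  read_block <- function(shp) {
    shp <- unlist(shp)
    v <- readBin(con, "double", n = prod(shp), size = 8L, endian = "little")
    if (length(shp) > 1L) array(v, shp) else v
  }
  ly$params <- lapply(h$params, read_block)
  ly$state <- if (length(h$state)) lapply(h$state, read_block) else NULL
  ly
}

#' Load a network saved with [write_network()]
#' @param prefix Path prefix used when saving.
#' @return A `"locomode_net"`.
#' @export
read_network <- function(prefix) {
  h <- jsonlite::read_json(paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  heads <- lapply(h$heads, function(hd) lapply(hd, read_layer_, con = con))
  trunk <- lapply(h$trunk, read_layer_, con = con)
  new_network(heads, trunk,
              lapply(h$input_shapes, function(s) as.integer(unlist(s))),
              unlist(h$n_classes), unlist(h$name))
}
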