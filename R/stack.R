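#' Layered simulation medium
#'
#' An ordered stack of homogeneous slabs bounded above by an ambient medium
#' (air by default). The last layer is always semi-infinite; every other
#' layer must have a finite positive thickness.
#'
#' @param ... One or more layers. Each layer is either an
#'   [optical_properties()] object (only valid for the final, semi-infinite
#'   layer) or a list `list(props =, thickness =)` with thickness in mm.
#' @param n_ambient Refractive index above the top surface (default 1.0).
#' @return An object of class `"layer_stack"`.
#' @examples
#' ref <- semi_infinite_stack(optics_from_ratio(100, lstar = 1))
#' @export
layer_stack <- function(..., n_ambient = 1.0) {
  raw <- list(...)
  if (length(raw) == 0L) stop("layer_stack needs at least one layer")
  if (!is.numeric(n_ambient) || n_ambient < 1)
    stop("n_ambient must be a refractive index >= 1")
  layers <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    li <- raw[[i]]
    last <- i == length(raw)
    if (inherits(li, "optical_properties")) {
      if (!last)
        stop("only the final layer may omit a thickness (it is semi-infinite)")
      layers[[i]] <- list(props = li, thickness = Inf)
    } else if (is.list(li) && inherits(li$props, "optical_properties")) {
      thick <- if (last) Inf else li$thickness
      if (!last && (!is.numeric(thick) || !is.finite(thick) || thick <= 0))
        stop(sprintf("layer %d: finite thickness > 0 required", i))
      layers[[i]] <- list(props = li$props, thickness = thick)
    } else {
      stop(sprintf(
        "layer %d must be optical_properties or list(props=, thickness=)", i))
    }
  }
  structure(list(layers = layers, n_ambient = n_ambient),
            class = "layer_stack")
}

#' @rdname layer_stack
#' @param props Optical properties of the single semi-infinite layer.
#' @export
semi_infinite_stack <- function(props, n_ambient = 1.0) {
  layer_stack(props, n_ambient = n_ambient)
}

#' Two-layer stack with a finite top layer
#'
#' Convenience constructor for the phantom geometry: a finite top slab over a
#' semi-infinite base.
#'
#' @param top,base [optical_properties()] of the two layers.
#' @param thickness Top-layer thickness (mm, > 0).
#' @param n_ambient Ambient refractive index.
#' @return A `"layer_stack"`.
#' @export
two_layer_stack <- function(top, thickness, base, n_ambient = 1.0) {
  layer_stack(list(props = top, thickness = thickness), base,
              n_ambient = n_ambient)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("Layer stack (%d layer%s, ambient n = %g):\n",
              length(x$layers), if (length(x$layers) > 1) "s" else "",
              x$n_ambient))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    p <- l$props
    cat(sprintf(
      "  [%d] mua = %g, mus = %g, g = %g, n = %g, thickness = %s mm\n",
      i, p$mua, p$mus, p$g, p$n,
      if (is.finite(l$thickness)) format(l$thickness) else "semi-infinite"))
  }
  invisible(x)
}

# matrix form consumed by the C++ kernel: columns mua, mus, g, n, thickness
as_layer_matrix <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  m <- t(vapply(stack$layers, function(l)
    c(l$props$mua, l$props$mus, l$props$g, l$props$n, l$thickness),
    numeric(5)))
  dimnames(m) <- list(NULL, c("mua", "mus", "g", "n", "thickness"))
  m
}

# serializable description (JSON sidecars, reproducibility records)
stack_to_list <- function(stack) {
  list(
    n_ambient = stack$n_ambient,
    layers = lapply(stack$layers, function(l)
      list(mua = l$props$mua, mus = l$props$mus, g = l$props$g,
           n = l$props$n, thickness = l$thickness)))
}

stack_from_list <- function(x) {
  ly <- x$layers
  # tolerate JSON simplification: rows of a data frame, "Inf" as a string
  if (is.data.frame(ly))
    ly <- lapply(seq_len(nrow(ly)), function(i) as.list(ly[i, ]))
  layers <- lapply(seq_along(ly), function(i) {
    li <- ly[[i]]
    thick <- li$thickness
    if (is.null(thick)) thick <- Inf
    thick <- suppressWarnings(as.numeric(thick))
    if (is.na(thick)) thick <- Inf
    list(props = optical_properties(as.numeric(li$mua), as.numeric(li$mus),
                                    as.numeric(li$g), as.numeric(li$n)),
         thickness = thick)
  })
  do.call(layer_stack, c(layers, list(n_ambient = as.numeric(x$n_ambient))))
}
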