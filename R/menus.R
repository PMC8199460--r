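# The four 7x7 menus of the asynchronous control paradigm. Every menu has
# exactly 49 cells; dummy cells are selectable but have no effect, keeping
# selection timing and chance level (1/49) identical across menus.

new_menu_layout <- function(name, grid, dummy) {
  stopifnot(
    is.matrix(grid), all(dim(grid) == c(7, 7)),
    is.matrix(dummy), all(dim(dummy) == c(7, 7))
  )
  structure(list(name = name, grid = grid, dummy = dummy),
    class = "menu_layout"
  )
}

#' @export
print.menu_layout <- function(x, ...) {
  cat("<menu_layout> ", x$name, " (", sum(x$dummy), " dummies)\n", sep = "")
  print(x$grid, quote = FALSE)
  invisible(x)
}

#' The four-menu catalog
#'
#' * `NC` (no control): 48 "X" dummies around a single central "IC" item,
#'   so a resting user leaves the state only by chance (1/49 per selection).
#' * `IC` (intentional control): ten commands (four send, three read,
#'   Reply, Cancel, NC) among 39 non-visible dummies.
#' * `Spelling`: a 6x6 block of the 26 letters and 10 digits, a seventh
#'   column of seven prediction slots (`PRED1`..`PRED7`), and a bottom row
#'   `SPC , Del. Del. W OK IC`.
#' * `Confirmation`: `Confirm` and `Back` among 47 dummies, guarding the
#'   buffer-clearing `OK`/`IC` selections.
#'
#' Exact grid positions of commands are configuration, not behavior; only
#' the cell inventory matters to the state machine.
#'
#' @return Named list of four `menu_layout` objects.
#' @export
menu_catalog <- function() {
  nc_grid <- matrix("X", 7, 7)
  nc_grid[4, 4] <- "IC"
  nc <- new_menu_layout("NC", nc_grid, nc_grid == "X")

  ic_grid <- matrix("", 7, 7)
  ic_grid[2, 2] <- "Send WA"
  ic_grid[2, 4] <- "Send TG"
  ic_grid[2, 6] <- "Send SMS"
  ic_grid[3, 2] <- "Send Mail"
  ic_grid[3, 4] <- "Read WA"
  ic_grid[3, 6] <- "Read TG"
  ic_grid[4, 2] <- "Read SMS"
  ic_grid[4, 4] <- "Reply"
  ic_grid[4, 6] <- "Cancel"
  ic_grid[5, 4] <- "NC"
  ic <- new_menu_layout("IC", ic_grid, ic_grid == "")

  sp_grid <- matrix("", 7, 7)
  sp_grid[1:5, 1:6] <- matrix(c(LETTERS, 0:3), 5, 6, byrow = TRUE)
  sp_grid[6, 1:6] <- as.character(4:9)
  sp_grid[1:7, 7] <- paste0("PRED", 1:7)
  sp_grid[7, 1:6] <- c("SPC", ",", "Del.", "Del. W", "OK", "IC")
  sp <- new_menu_layout("Spelling", sp_grid, matrix(FALSE, 7, 7))

  cf_grid <- matrix("", 7, 7)
  cf_grid[4, 3] <- "Confirm"
  cf_grid[4, 5] <- "Back"
  cf <- new_menu_layout("Confirmation", cf_grid, cf_grid == "")

  list(NC = nc, IC = ic, Spelling = sp, Confirmation = cf)
}

#' Locate an item in a menu layout
#'
#' @param layout A `menu_layout`.
#' @param label Item label.
#' @return 0-based `c(row, col)` of the first matching cell, or `NULL`.
#' @export
locate_item <- function(layout, label) {
  hit <- which(layout$grid == label, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(NULL)
  }
  c(hit[1, "row"] - 1L, hit[1, "col"] - 1L)
}

#' @rdname locate_item
#' @param row,col 0-based cell indices.
#' @return `item_at()`: the label of a cell.
#' @export
item_at <- function(layout, row, col) {
  layout$grid[row + 1L, col + 1L]
}
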