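# R-tree spatial index: maps (chromosome id, base range) queries to the
# file offsets of the data sections that may overlap them.  Built bottom-up
# over the sorted section bookkeeping ("leaf items"), packed with at most
# `blockSize` children per node.  Magic 0x2468ACE0; 48-byte index header;
# 4-byte node headers; 32-byte leaf and 24-byte internal items.

RTREE_MAGIC <- 610839776   # 0x2468ACE0

# lexicographic (chromId, base) comparison helpers over parallel vectors
.lexLt <- function(c1, b1, c2, b2) c1 < c2 | (c1 == c2 & b1 < b2)

# leaves: data.frame(id, start, end, offset, size), sorted by (id, start).
# Returns the serialized index block for absolute file offset `atOffset`.
buildRTree <- function(leaves, atOffset = 0, blockSize = 256L,
                       itemsPerSlot = 1024L, endFileOffset = 0,
                       endian = "little") {
  n <- nrow(leaves)
  if (!n) bbiValidationError("cannot build an R-tree over zero items")
  if (blockSize < 2L) bbiValidationError("R-tree branching must be >= 2")
  o <- order(leaves$id, leaves$start)
  if (!identical(o, seq_len(n)))
    bbiValidationError("R-tree leaf items must be sorted by (chrom id, start)")

  # per-node bounds as lexicographic (id,start) min and (id,end) max
  nodeBounds <- function(sC, sB, eC, eB, groups) {
    t(vapply(groups, function(g) {
      mx <- g[eC[g] == max(eC[g])]
      c(sC[g[1L]], sB[g[1L]], max(eC[g]), max(eB[mx]))
    }, c(0, 0, 0, 0)))
  }

  levels <- list(blockGroups(n, blockSize))
  bounds <- list(nodeBounds(leaves$id, leaves$start, leaves$id, leaves$end,
                            levels[[1L]]))
  while (length(levels[[length(levels)]]) > 1L) {
    g <- blockGroups(length(levels[[length(levels)]]), blockSize)
    b <- bounds[[length(bounds)]]
    levels <- c(levels, list(g))
    bounds <- c(bounds, list(nodeBounds(b[, 1L], b[, 2L], b[, 3L], b[, 4L],
                                        g)))
  }
  levels <- rev(levels); bounds <- rev(bounds)  # root first
  nLevels <- length(levels)
  nodeSize <- function(li, cnt) 4 + cnt * if (li == nLevels) 32 else 24
  offs <- vector("list", nLevels)
  cur <- atOffset + 48
  for (li in seq_len(nLevels)) {
    cnts <- lengths(levels[[li]])
    sizes <- nodeSize(li, cnts)
    offs[[li]] <- cur + cumsum(c(0, head(sizes, -1)))
    cur <- cur + sum(sizes)
  }
  rootB <- bounds[[1L]][1L, ]
  if (nLevels == 1L) rootB <- c(leaves$id[1L], leaves$start[1L],
                                bounds[[1L]][1L, 3L], bounds[[1L]][1L, 4L])
  # whole-tree bounds = bounds of the root's children collectively
  allB <- bounds[[1L]]
  treeB <- c(allB[1L, 1L], allB[1L, 2L],
             allB[which.max(allB[, 3L] * 2^33 + allB[, 4L]), 3L],
             max(allB[allB[, 3L] == max(allB[, 3L]), 4L]))
  out <- list(c(u32ToRaw(RTREE_MAGIC, endian), u32ToRaw(blockSize, endian),
                u64ToRaw(n, endian),
                u32ToRaw(treeB[1L], endian), u32ToRaw(treeB[2L], endian),
                u32ToRaw(treeB[3L], endian), u32ToRaw(treeB[4L], endian),
                u64ToRaw(endFileOffset, endian),
                u32ToRaw(itemsPerSlot, endian), u32ToRaw(0, endian)))
  k <- 1L
  for (li in seq_len(nLevels)) {
    isLeaf <- li == nLevels
    for (ni in seq_along(levels[[li]])) {
      g <- levels[[li]][[ni]]
      k <- k + 1L
      out[[k]] <- if (isLeaf)
        c(u8ToRaw(1), u8ToRaw(0), u16ToRaw(length(g), endian),
          as.raw(rbind(matrix(u32ToRaw(leaves$id[g], endian), nrow = 4),
                       matrix(u32ToRaw(leaves$start[g], endian), nrow = 4),
                       matrix(u32ToRaw(leaves$id[g], endian), nrow = 4),
                       matrix(u32ToRaw(leaves$end[g], endian), nrow = 4),
                       matrix(u64ToRaw(leaves$offset[g], endian), nrow = 8),
                       matrix(u64ToRaw(leaves$size[g], endian), nrow = 8))))
      else {
        cb <- bounds[[li + 1L]][g, , drop = FALSE]
        c(u8ToRaw(0), u8ToRaw(0), u16ToRaw(length(g), endian),
          as.raw(rbind(matrix(u32ToRaw(cb[, 1L], endian), nrow = 4),
                       matrix(u32ToRaw(cb[, 2L], endian), nrow = 4),
                       matrix(u32ToRaw(cb[, 3L], endian), nrow = 4),
                       matrix(u32ToRaw(cb[, 4L], endian), nrow = 4),
                       matrix(u64ToRaw(offs[[li + 1L]][g], endian),
                              nrow = 8))))
      }
    }
  }
  unlist(out)
}

readRTreeHeader <- function(src, offset, endian = "little") {
  hdr <- sourceReadExact(src, offset, 48)
  if (rawToU32(hdr[1:4], 1, endian) != RTREE_MAGIC)
    bbiFormatError("bad R-tree magic", offset = offset)
  list(blockSize = rawToU32(hdr[5:8], 1, endian),
       itemCount = rawToU64(hdr[9:16], 1, endian),
       startChromIx = rawToU32(hdr[17:20], 1, endian),
       startBase = rawToU32(hdr[21:24], 1, endian),
       endChromIx = rawToU32(hdr[25:28], 1, endian),
       endBase = rawToU32(hdr[29:32], 1, endian),
       endFileOffset = rawToU64(hdr[33:40], 1, endian),
       itemsPerSlot = rawToU32(hdr[41:44], 1, endian))
}

# Query the index rooted at `offset` for blocks overlapping [start, end)
# on chromosome `id`.  Only nodes whose bounds overlap are visited, so
# blocks touched is O(log n + hits).  Returns data.frame(offset, size) in
# file order.
queryRTree <- function(src, offset, id, start, end, endian = "little") {
  readRTreeHeader(src, offset, endian)   # validates magic
  readNode <- function(off) {
    h <- sourceReadExact(src, off, 4)
    isLeaf <- rawToU8(h[1L])
    cnt <- rawToU16(h[3:4], 1, endian)
    if (!isLeaf %in% c(0, 1))
      bbiFormatError("corrupt R-tree node", offset = off)
    if (cnt == 0) return(NULL)
    if (isLeaf == 1) {
      body <- sourceReadExact(src, off + 4, cnt * 32)
      m <- matrix(body, nrow = 32)
      sC <- rawToU32(as.raw(m[1:4, ]), cnt, endian)
      sB <- rawToU32(as.raw(m[5:8, ]), cnt, endian)
      eC <- rawToU32(as.raw(m[9:12, ]), cnt, endian)
      eB <- rawToU32(as.raw(m[13:16, ]), cnt, endian)
      hit <- .lexLt(sC, sB, id, end) & .lexLt(id, start, eC, eB)
      if (!any(hit)) return(NULL)
      data.frame(offset = rawToU64(as.raw(m[17:24, hit, drop = FALSE]),
                                   sum(hit), endian),
                 size = rawToU64(as.raw(m[25:32, hit, drop = FALSE]),
                                 sum(hit), endian))
    } else {
      body <- sourceReadExact(src, off + 4, cnt * 24)
      m <- matrix(body, nrow = 24)
      sC <- rawToU32(as.raw(m[1:4, ]), cnt, endian)
      sB <- rawToU32(as.raw(m[5:8, ]), cnt, endian)
      eC <- rawToU32(as.raw(m[9:12, ]), cnt, endian)
      eB <- rawToU32(as.raw(m[13:16, ]), cnt, endian)
      kids <- rawToU64(as.raw(m[17:24, ]), cnt, endian)
      hit <- .lexLt(sC, sB, id, end) & .lexLt(id, start, eC, eB)
      if (!any(hit)) return(NULL)
      do.call(rbind, lapply(kids[hit], readNode))
    }
  }
  out <- readNode(offset + 48)
  if (is.null(out)) data.frame(offset = double(), size = double()) else out
}

# Enumerate every leaf item of the index, in file (coordinate) order;
# used for whole-file streaming and inspection.
rtreeLeaves <- function(src, offset, endian = "little") {
  readRTreeHeader(src, offset, endian)
  readNode <- function(off) {
    h <- sourceReadExact(src, off, 4)
    isLeaf <- rawToU8(h[1L])
    cnt <- rawToU16(h[3:4], 1, endian)
    if (!isLeaf %in% c(0, 1))
      bbiFormatError("corrupt R-tree node", offset = off)
    if (cnt == 0) return(NULL)
    if (isLeaf == 1) {
      m <- matrix(sourceReadExact(src, off + 4, cnt * 32), nrow = 32)
      data.frame(id = rawToU32(as.raw(m[1:4, ]), cnt, endian),
                 start = rawToU32(as.raw(m[5:8, ]), cnt, endian),
                 endId = rawToU32(as.raw(m[9:12, ]), cnt, endian),
                 end = rawToU32(as.raw(m[13:16, ]), cnt, endian),
                 offset = rawToU64(as.raw(m[17:24, ]), cnt, endian),
                 size = rawToU64(as.raw(m[25:32, ]), cnt, endian))
    } else {
      m <- matrix(sourceReadExact(src, off + 4, cnt * 24), nrow = 24)
      kids <- rawToU64(as.raw(m[17:24, ]), cnt, endian)
      do.call(rbind, lapply(kids, readNode))
    }
  }
  out <- readNode(offset + 48)
  if (is.null(out))
    data.frame(id = double(), start = double(), endId = double(),
               end = double(), offset = double(), size = double())
  else out
}
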