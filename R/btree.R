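# Chromosome B+ tree: fixed-width name -> (id, size) index embedded in
# every BBI file.  Keys are chromosome names padded with NULs to the
# longest name; entries are key-sorted (byte order), while chromosome ids
# keep the chrom.sizes input order.  Magic 0x78CA8C91.

BPT_MAGIC <- 2026540177   # 0x78CA8C91

# pad names to keySize bytes, as a raw matrix with one column per name
packKeys <- function(names, keySize) {
  m <- matrix(as.raw(0L), nrow = keySize, ncol = length(names))
  for (i in seq_along(names)) {
    r <- charToRaw(names[i])
    m[seq_along(r), i] <- r
  }
  m
}

# group indices 1..n into consecutive blocks of at most blockSize
blockGroups <- function(n, blockSize)
  split(seq_len(n), ceiling(seq_len(n) / blockSize))

# Serialize the B+ tree for a ChromSizes, to live at absolute file offset
# `atOffset` (child pointers are absolute).  Returns the raw block.
buildChromBTree <- function(cs, atOffset = 0, blockSize = 256L,
                            endian = "little") {
  n <- length(cs)
  if (!n) bbiValidationError("cannot index an empty chromosome set")
  keySize <- max(nchar(cs@chrom, type = "bytes"))
  ord <- order(cs@chrom, method = "radix")
  keys <- packKeys(cs@chrom[ord], keySize)
  ids <- ord - 1          # id = position in chrom.sizes order
  sizes <- cs@size[ord]

  # levels[[1]] = leaf nodes (lists of item indices); higher levels group
  # nodes of the level below
  levels <- list(blockGroups(n, blockSize))
  while (length(levels[[length(levels)]]) > 1L)
    levels <- c(levels, list(blockGroups(length(levels[[length(levels)]]),
                                         blockSize)))
  levels <- rev(levels)   # root first
  itemBytes <- keySize + 8
  nodeSize <- function(cnt) 4 + cnt * itemBytes
  # absolute offset of every node, laid out root-level first
  offs <- vector("list", length(levels))
  cur <- atOffset + 32
  for (li in seq_along(levels)) {
    cnts <- lengths(levels[[li]])
    offs[[li]] <- cur + cumsum(c(0, head(nodeSize(cnts), -1)))
    cur <- cur + sum(nodeSize(cnts))
  }
  out <- list(c(u32ToRaw(BPT_MAGIC, endian), u32ToRaw(blockSize, endian),
                u32ToRaw(keySize, endian), u32ToRaw(8, endian),
                u64ToRaw(n, endian), u64ToRaw(0, endian)))
  # key that represents a subtree = key of its first (lowest) item
  firstItem <- function(li, ni) {
    while (li < length(levels)) { ni <- levels[[li]][[ni]][1L]; li <- li + 1L }
    levels[[li]][[ni]][1L]
  }
  k <- 1L
  for (li in seq_along(levels)) {
    isLeaf <- li == length(levels)
    for (ni in seq_along(levels[[li]])) {
      g <- levels[[li]][[ni]]
      k <- k + 1L
      out[[k]] <- if (isLeaf)
        c(u8ToRaw(1), u8ToRaw(0), u16ToRaw(length(g), endian),
          as.raw(rbind(keys[, g, drop = FALSE],
                       matrix(u32ToRaw(ids[g], endian), nrow = 4),
                       matrix(u32ToRaw(sizes[g], endian), nrow = 4))))
      else
        c(u8ToRaw(0), u8ToRaw(0), u16ToRaw(length(g), endian),
          as.raw(rbind(keys[, vapply(g, function(x) firstItem(li + 1L, x), 1L),
                            drop = FALSE],
                       matrix(u64ToRaw(offs[[li + 1L]][g], endian),
                              nrow = 8))))
    }
  }
  unlist(out)
}

# Parse the whole chromosome B+ tree into a data.frame(chrom, id, size),
# in key (name) order.
readChromBTree <- function(src, offset, endian = "little") {
  hdr <- sourceReadExact(src, offset, 32)
  if (rawToU32(hdr[1:4], 1, endian) != BPT_MAGIC)
    bbiFormatError("bad chromosome B+ tree magic", offset = offset)
  keySize <- rawToU32(hdr[9:12], 1, endian)
  valSize <- rawToU32(hdr[13:16], 1, endian)
  if (valSize != 8)
    bbiFormatError("unexpected chromosome B+ tree value size",
                   offset = offset)
  itemBytes <- keySize + 8
  readNode <- function(off) {
    h <- sourceReadExact(src, off, 4)
    isLeaf <- rawToU8(h[1L])
    cnt <- rawToU16(h[3:4], 1, endian)
    if (!isLeaf %in% c(0, 1))
      bbiFormatError("corrupt B+ tree node", offset = off)
    body <- sourceReadExact(src, off + 4, cnt * itemBytes)
    m <- matrix(body, nrow = itemBytes)
    keys <- apply(m[seq_len(keySize), , drop = FALSE], 2, function(r)
      rawToChar(r[r != as.raw(0)]))
    if (isLeaf == 1) {
      data.frame(chrom = as.character(keys),
                 id = rawToU32(as.raw(m[keySize + (1:4), ]), cnt, endian),
                 size = rawToU32(as.raw(m[keySize + (5:8), ]), cnt, endian))
    } else {
      kids <- rawToU64(as.raw(m[keySize + (1:8), ]), cnt, endian)
      do.call(rbind, lapply(kids, readNode))
    }
  }
  readNode(offset + 32)
}

# name lookup against the parsed table: (id, size) or NULL when absent
bptLookup <- function(chromTable, chrom) {
  i <- match(chrom, chromTable$chrom)
  if (is.na(i)) return(NULL)
  list(id = chromTable$id[i], size = chromTable$size[i])
}
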