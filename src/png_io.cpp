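// Minimal PNG codec (8-bit greyscale / RGB / RGBA, non-interlaced).
// No R image package is available in this environment, so the standard
// container formats are handled here directly on top of zlib.
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void write_chunk(std::vector<unsigned char>& out, const char* type,
                        const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  put_u32(out, (uint32_t)crc);
}

// img: numeric array H x W x C (C in {1,3,4}) with values in [0,1]
// [[Rcpp::export(name = ".cpp_write_png")]]
void cpp_write_png(std::string path, NumericVector img, int height, int width,
                   int channels) {
  if (channels != 1 && channels != 3 && channels != 4)
    stop("PNG writer supports 1, 3 or 4 channels");
  const int bpp = channels;
  // raw scanlines with filter byte 0
  std::vector<unsigned char> raw((size_t)height * (1 + (size_t)width * bpp));
  size_t pos = 0;
  const double* d = img.begin();
  const size_t plane = (size_t)height * width;
  for (int r = 0; r < height; ++r) {
    raw[pos++] = 0;  // filter: none
    for (int c = 0; c < width; ++c) {
      for (int ch = 0; ch < channels; ++ch) {
        double v = d[(size_t)ch * plane + (size_t)c * height + r];
        if (v < 0) v = 0;
        if (v > 1) v = 1;
        raw[pos++] = (unsigned char)(v * 255.0 + 0.5);
      }
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(clen);

  std::vector<unsigned char> out(PNG_SIG, PNG_SIG + 8);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)width);
  put_u32(ihdr, (uint32_t)height);
  ihdr.push_back(8);  // bit depth
  ihdr.push_back(channels == 1 ? 0 : (channels == 3 ? 2 : 6));  // color type
  ihdr.push_back(0);
  ihdr.push_back(0);
  ihdr.push_back(0);  // no interlace
  write_chunk(out, "IHDR", ihdr);
  write_chunk(out, "IDAT", comp);
  write_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b),
      pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".cpp_read_png")]]
List cpp_read_png(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long n = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)n);
  if (std::fread(buf.data(), 1, (size_t)n, f) != (size_t)n) {
    std::fclose(f);
    stop("short read on '%s'", path.c_str());
  }
  std::fclose(f);
  if (n < 8 || std::memcmp(buf.data(), PNG_SIG, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());

  size_t off = 8;
  int width = 0, height = 0, bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  while (off + 8 <= (size_t)n) {
    uint32_t len = get_u32(&buf[off]);
    std::string type((char*)&buf[off + 4], 4);
    const unsigned char* data = &buf[off + 8];
    if (type == "IHDR") {
      width = get_u32(data);
      height = get_u32(data + 4);
      bit_depth = data[8];
      color_type = data[9];
      interlace = data[12];
    } else if (type == "IDAT") {
      idat.insert(idat.end(), data, data + len);
    } else if (type == "IEND") {
      break;
    }
    off += 12 + len;
  }
  if (bit_depth != 8) stop("only 8-bit PNGs supported");
  if (interlace != 0) stop("interlaced PNGs not supported");
  int channels;
  switch (color_type) {
    case 0: channels = 1; break;
    case 2: channels = 3; break;
    case 4: channels = 2; break;
    case 6: channels = 4; break;
    default: stop("unsupported PNG color type %d (palette?)", color_type);
  }
  const int bpp = channels;
  size_t stride = (size_t)width * bpp;
  std::vector<unsigned char> raw((size_t)height * (stride + 1));
  uLongf rlen = (uLongf)raw.size();
  if (uncompress(raw.data(), &rlen, idat.data(), (uLong)idat.size()) != Z_OK ||
      rlen != raw.size())
    stop("PNG inflate failed");

  // undo per-scanline filters in place
  std::vector<unsigned char> prev(stride, 0), cur(stride);
  NumericVector out((size_t)height * width * channels);
  const size_t plane = (size_t)height * width;
  for (int r = 0; r < height; ++r) {
    unsigned char ft = raw[(size_t)r * (stride + 1)];
    const unsigned char* src = &raw[(size_t)r * (stride + 1) + 1];
    for (size_t i = 0; i < stride; ++i) {
      int a = i >= (size_t)bpp ? cur[i - bpp] : 0;
      int b = prev[i];
      int c = i >= (size_t)bpp ? prev[i - bpp] : 0;
      int x = src[i];
      switch (ft) {
        case 0: cur[i] = (unsigned char)x; break;
        case 1: cur[i] = (unsigned char)(x + a); break;
        case 2: cur[i] = (unsigned char)(x + b); break;
        case 3: cur[i] = (unsigned char)(x + ((a + b) >> 1)); break;
        case 4: cur[i] = (unsigned char)(x + paeth(a, b, c)); break;
        default: stop("bad PNG filter type %d", (int)ft);
      }
    }
    for (int ccol = 0; ccol < width; ++ccol)
      for (int ch = 0; ch < channels; ++ch)
        out[(size_t)ch * plane + (size_t)ccol * height + r] =
            cur[(size_t)ccol * bpp + ch] / 255.0;
    std::swap(prev, cur);
  }
  return List::create(_["pixels"] = out, _["height"] = height,
                      _["width"] = width, _["channels"] = channels);
}
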