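// Streaming fixed-point kernels: the per-sample feature state machines, the
// exponentially decaying moving average (EMA), and the decision debounce.
//
// All integer arithmetic is carried in doubles, which represent every integer
// up to 2^53 exactly; the values handled here (feature accumulators <= 2^16-1,
// smoothed signals < 2^32, intermediate products < 2^40) stay far below that,
// so the floor/shift semantics below are bit-exact two's-complement behaviour.

#include <Rcpp.h>
#include <cmath>
#include <string>
using namespace Rcpp;

static const double I32_MAX = 2147483647.0;
static const double EXACT_INT_MAX = 9007199254740992.0; // 2^53

// floor((v * m) / 2^k): a hardware multiply followed by an arithmetic right
// shift (truncation toward -Inf for negative values).
static inline double fx(double v, double m, int k) {
  return std::floor(std::ldexp(v * m, -k));
}

// [[Rcpp::export(name = ".fx_scale_cpp")]]
NumericVector fx_scale_cpp(NumericVector v, double m, int k) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[i];
    if (!R_finite(vi) || std::fabs(vi) > I32_MAX)
      stop("fixed-point value outside the signed 32-bit range");
    double p = vi * m;
    if (std::fabs(p) > EXACT_INT_MAX)
      stop("intermediate product overflows the 64-bit fixed-point range");
    out[i] = std::floor(std::ldexp(p, -k));
  }
  return out;
}

struct Coef {
  double m;  // multiplier
  int k;     // shift
  double t;  // real-valued target (reference path)
};

static Coef get_coef(const List& p, const std::string& base) {
  Coef c;
  c.m = as<double>(p[base + "_m"]);
  c.k = as<int>(p[base + "_k"]);
  c.t = as<double>(p[base + "_t"]);
  return c;
}

// One scale operation. The fixed path uses the quantized multiplier/shift
// pair; the reference path uses the real coefficient. Both truncate toward
// -Inf, mirroring the original design flow in which the reference
// implementation modelled the hardware truncation.
static inline double sc(double v, const Coef& c, bool fixed) {
  return fixed ? fx(v, c.m, c.k) : std::floor(v * c.t);
}

enum Family { ZCR, MCR, SSC, WFL, MAV1, MAV2, WAM1, WAM2, VAR };

static Family family_code(const std::string& f) {
  if (f == "zcr") return ZCR;
  if (f == "mcr") return MCR;
  if (f == "ssc") return SSC;
  if (f == "wfl") return WFL;
  if (f == "mav1") return MAV1;
  if (f == "mav2") return MAV2;
  if (f == "wam1") return WAM1;
  if (f == "wam2") return WAM2;
  if (f == "var") return VAR;
  stop("unknown feature family '%s'", f.c_str());
}

// Run one feature state machine over a block of samples. `state` round-trips
// through R unchanged in precision, so chunked (streaming) execution is
// bit-identical to one batch call.
// [[Rcpp::export(name = ".feature_run_cpp")]]
List feature_run_cpp(NumericVector x, List params, List state, bool fixed) {
  Family fam = family_code(as<std::string>(params["family"]));
  Coef b = get_coef(params, "b");
  Coef c = get_coef(params, "c");
  Coef d = get_coef(params, "d");
  Coef e = get_coef(params, "e");
  int delay = as<int>(params["delay"]);
  double hyst = as<double>(params["hyst"]);
  double lb = as<double>(params["lb"]);
  double ub = as<double>(params["ub"]);
  double dmin = as<double>(params["dmin"]);
  double dmax = as<double>(params["dmax"]);
  double thresh = as<double>(params["thresh"]);
  double upd = as<double>(params["update"]);
  double ub1 = as<double>(params["ub1"]);

  double feat = as<double>(state["feat"]);
  double smo = as<double>(state["smo"]);
  int s = as<int>(state["s"]);
  double w = as<double>(state["w"]);
  double p = as<double>(state["p"]);
  double aux = as<double>(state["aux"]);
  NumericVector buf = clone(as<NumericVector>(state["buf"]));
  int pos = as<int>(state["pos"]);

  const Coef& outer = (fam == MAV2) ? c : b;  // MAV2's outer EMA uses c
  int n = x.size();
  NumericVector out(n);

  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    if (!R_finite(xi) || std::fabs(xi) > I32_MAX)
      stop("input sample outside the signed 32-bit range");
    double f = 0.0;

    switch (fam) {
    case ZCR:
      if (xi > hyst && s == 0) { f = upd; s = 1; }
      else if (xi < -hyst && s == 1) { f = upd; s = 0; }
      break;
    case MCR: {
      smo = sc(smo + xi, c, fixed);
      double v = sc(smo, e, fixed);
      double xD = sc(delay > 0 ? buf[pos] : xi, d, fixed);
      if (xD > v + hyst && s == 0) { f = upd; s = 1; }
      else if (xD < v - hyst && s == 1) { f = upd; s = 0; }
      if (delay > 0) { buf[pos] = xi; pos = (pos + 1) % delay; }
      break;
    }
    case SSC: {
      // strict if/else-if cascade, evaluated exactly in this order
      double u = smo;
      smo = sc(smo + xi, c, fixed);
      double v = smo;
      if (v > u && s == 0 && w >= dmin && p < dmax) { f = upd; s = 1; w = 0; p = 0; }
      else if (v > u && s == 0 && w >= dmin) { s = 1; w = 0; p = 0; }
      else if (v > u && s == 0) { w += 1; }
      else if (v > u) { s = 1; w = 0; p += 1; }
      else if (v < u && s == 1 && w >= dmin && p < dmax) { f = upd; s = 0; w = 0; p = 0; }
      else if (v < u && s == 1 && w >= dmin) { s = 0; w = 0; p = 0; }
      else if (v < u && s == 1) { w += 1; }
      else { s = 0; w = 0; p += 1; }
      break;
    }
    case WFL:
      f = sc(std::fabs(xi - buf[0]), d, fixed);
      buf[0] = xi;
      break;
    case MAV1:
      f = std::fabs(xi);
      break;
    case MAV2: {
      // internal MAV1 recursion (coefficient b, bound ub1) feeds the outer EMA
      aux = sc(aux + std::fabs(xi), b, fixed);
      if (aux < 0) aux = 0;
      if (aux > ub1) aux = ub1;
      double past = delay > 0 ? buf[pos] : aux;
      f = std::fabs(aux - past);
      if (delay > 0) { buf[pos] = aux; pos = (pos + 1) % delay; }
      break;
    }
    case WAM1:
      if (std::fabs(xi) > thresh) f = upd;
      break;
    case WAM2: {
      smo = sc(smo + xi, c, fixed);
      double xD = sc(delay > 0 ? buf[pos] : xi, d, fixed);
      if (std::fabs(xD - smo) > thresh) f = upd;
      if (delay > 0) { buf[pos] = xi; pos = (pos + 1) % delay; }
      break;
    }
    case VAR:
      f = xi * xi;
      break;
    }

    feat = sc(feat + f, outer, fixed);
    if (feat < lb) feat = lb;
    if (feat > ub) feat = ub;
    out[i] = feat;
  }

  return List::create(
    _["values"] = out,
    _["state"] = List::create(
      _["feat"] = feat, _["smo"] = smo, _["s"] = s, _["w"] = w,
      _["p"] = p, _["aux"] = aux, _["buf"] = buf, _["pos"] = pos));
}

// Plain EMA stream y_i = saturate(floor((y_{i-1} + f_i) * b)), used for the
// rectified envelope.
// [[Rcpp::export(name = ".ema_run_cpp")]]
List ema_run_cpp(NumericVector f, double m, int k, double target, bool fixed,
                 double init, double lb, double ub) {
  int n = f.size();
  NumericVector out(n);
  double y = init;
  Coef c; c.m = m; c.k = k; c.t = target;
  for (int i = 0; i < n; ++i) {
    y = sc(y + f[i], c, fixed);
    if (y < lb) y = lb;
    if (y > ub) y = ub;
    out[i] = y;
  }
  return List::create(_["values"] = out, _["state"] = y);
}

// Decision debounce: the output switches to a new class only after observing
// strictly more than n_slope consecutive decisions of that class (or exactly
// n_slope when strict = false); any interruption resets the run counter.
// [[Rcpp::export(name = ".debounce_cpp")]]
IntegerVector debounce_cpp(IntegerVector d, int nslope, int init, bool strict) {
  int n = d.size();
  IntegerVector out(n);
  int o = init, cnt = 0;
  for (int i = 0; i < n; ++i) {
    int di = d[i];
    if (di == o) {
      cnt = 0;
    } else {
      ++cnt;
      if (strict ? (cnt > nslope) : (cnt >= nslope)) { o = di; cnt = 0; }
    }
    out[i] = o;
  }
  return out;
}
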