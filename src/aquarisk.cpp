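#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Manning discharge (m^3/h) for a trapezoidal channel at depth d.
// A = d (b + s d); P = b + 2 d sqrt(1 + s^2); Q = (1/n) A R^{2/3} S^{1/2}.
static inline double manning_q(double d, double b, double s, double n,
                               double S) {
  if (d <= 0.0) return 0.0;
  double A = d * (b + s * d);
  double P = b + 2.0 * d * std::sqrt(1.0 + s * s);
  if (A <= 0.0 || P <= 0.0) return 0.0;
  double R = A / P;
  return (1.0 / n) * A * std::pow(R, 2.0 / 3.0) * std::sqrt(S) * 3600.0;
}

// Bisection for normal depth; Q monotone in d makes the bracket safe.
static double manning_depth_one(double Q, double b, double s, double n,
                                double S, double floor_depth, double tol,
                                double dmax) {
  if (Q <= manning_q(floor_depth, b, s, n, S)) return floor_depth;
  double lo = floor_depth, hi = dmax;
  if (Q > manning_q(dmax, b, s, n, S)) {
    stop("Manning depth solver: discharge %f m^3/h exceeds capacity of "
         "bracket [%f, %f] m (b=%f, s=%f, n=%f, S=%f)",
         Q, floor_depth, dmax, b, s, n, S);
  }
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    if (manning_q(mid, b, s, n, S) < Q) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
NumericVector manning_depth_cpp(NumericVector Q, double bottom_width,
                                double bank_slope, double manning_n,
                                double slope, double floor_depth,
                                double tol, double dmax) {
  int m = Q.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    if (Q[i] < 0) stop("discharge must be >= 0");
    out[i] = manning_depth_one(Q[i], bottom_width, bank_slope, manning_n,
                               slope, floor_depth, tol, dmax);
  }
  return out;
}

// (1 - exp(-a T)) / a, stable for small a
static inline double gdecay(double a, double T) {
  double x = a * T;
  if (x < 1e-8) return T * (1.0 - 0.5 * x + x * x / 6.0);
  return -std::expm1(-x) / a;
}

// Exact one-hour update of the linear water/sediment pair
//   dW/dt = -alpha W + beta S
//   dS/dt =  gamma W - delta S
// returning new state and the time integrals of W and S over the step.
struct StepOut {
  double W1, S1, Iw, Is;
};

static StepOut linear_step(double W0, double S0, double alpha, double beta,
                           double gamma, double delta, double T) {
  double m = 0.5 * (alpha + delta);
  double h = 0.5 * (alpha - delta);
  double q2 = h * h + beta * gamma;
  double q = q2 > 0.0 ? std::sqrt(q2) : 0.0;
  double a = m - q, b = m + q; // decay eigenvalues, both >= 0

  double ea = std::exp(-a * T), eb = std::exp(-b * T);
  double coshq = 0.5 * (ea + eb);              // e^{-mT} cosh(qT)
  double shq;                                  // e^{-mT} sinh(qT)/q
  if (q * T > 1e-7) {
    shq = 0.5 * (ea - eb) / q;
  } else {
    // sinh(qT)/q ~ T (1 + (qT)^2/6); prefactor e^{-mT}
    shq = std::exp(-m * T) * T * (1.0 + q2 * T * T / 6.0);
  }
  StepOut o;
  // expm(-M T) entries; (m I - M) = [[m-alpha, beta],[gamma, m-delta]]
  o.W1 = coshq * W0 + shq * ((m - alpha) * W0 + beta * S0);
  o.S1 = coshq * S0 + shq * (gamma * W0 + (m - delta) * S0);

  double ga = gdecay(a, T), gb = gdecay(b, T);
  double Icosh = 0.5 * (ga + gb);
  double Ish;
  if (q * T > 1e-7) {
    Ish = 0.5 * (ga - gb) / q;
  } else {
    // -d g/da at a=m: (e^{-mT}(mT+1) - 1)/m^2, small-m safe
    double x = m * T;
    if (x < 1e-8) {
      Ish = 0.5 * T * T * (1.0 - 2.0 * x / 3.0);
    } else {
      Ish = (std::exp(-x) * (x + 1.0) - 1.0) / (m * m) * (-1.0);
    }
  }
  o.Iw = Icosh * W0 + Ish * ((m - alpha) * W0 + beta * S0);
  o.Is = Icosh * S0 + Ish * (gamma * W0 + (m - delta) * S0);
  if (o.W1 < 0.0 || o.S1 < 0.0 || o.Iw < 0.0 || o.Is < 0.0) {
    stop("fate step produced a negative mass (W1=%g S1=%g); "
         "this indicates a numerical defect", o.W1, o.S1);
  }
  return o;
}

// [[Rcpp::export]]
List linear_step_cpp(double W0, double S0, double alpha, double beta,
                     double gamma, double delta, double T) {
  StepOut o = linear_step(W0, S0, alpha, beta, gamma, delta, T);
  return List::create(_["W1"] = o.W1, _["S1"] = o.S1,
                      _["Iw"] = o.Iw, _["Is"] = o.Is);
}

// Hourly network routing: reaches are processed in topological order within
// each hour; the advected outflow of a reach enters its downstream
// neighbour in the same hour. Hydrology (catchment-area-yield discharge,
// Manning depth, volume) is computed on the fly from the outlet series.
// [[Rcpp::export]]
List route_kernel_cpp(IntegerVector topo,       // 0-based processing order
                      IntegerVector down,       // 0-based downstream, -1 outlet
                      NumericVector len, NumericVector bw, NumericVector bs,
                      NumericVector mn, NumericVector sl,
                      NumericVector area_ratio,
                      NumericVector q_outlet,   // m^3/h per hour
                      NumericVector temp_day,   // degC per day (3-day mean)
                      IntegerVector drift_hour, // sorted, 0-based
                      IntegerVector drift_reach,
                      NumericVector drift_mass, // ug
                      List subst,
                      double floor_depth, double depth_tol, double depth_max,
                      int assess_start_hour, bool keep_sediment,
                      Nullable<NumericMatrix> Q_ext = R_NilValue,
                      Nullable<NumericMatrix> V_ext = R_NilValue) {
  const int n = len.size();
  const int n_hours = q_outlet.size();
  const int n_out = n_hours - assess_start_hour;
  if (n_out <= 0) stop("assessment period is empty");

  const double koc = as<double>(subst["koc"]);
  const double dt50w = as<double>(subst["dt50_water"]);
  const double dt50s = as<double>(subst["dt50_sediment"]);
  const double Tref = as<double>(subst["ref_temp"]) + 273.15;
  const double Ea = as<double>(subst["molar_activation_energy"]) * 1000.0;
  const double kvol_d = as<double>(subst["volatilization_rate"]);
  const double vex = as<double>(subst["sed_exchange_velocity"]);
  const double foc_ss = as<double>(subst["foc_suspended"]);
  const double foc_sed = as<double>(subst["foc_sediment"]);
  const double ss = as<double>(subst["suspended_solids"]);
  const double sed_depth = as<double>(subst["sediment_depth"]);
  const double poros = as<double>(subst["sediment_porosity"]);
  const double rho_b = as<double>(subst["sediment_bulk_density"]); // kg/L

  const double fd = 1.0 / (1.0 + koc * foc_ss * ss);
  const double kdegw_ref = M_LN2 / dt50w / 24.0; // 1/h at ref temp
  const double kdegs_ref = M_LN2 / dt50s / 24.0;
  const double kvol_h = kvol_d / 24.0 * fd;      // acts on dissolved fraction
  const double Rgas = 8.314;

  // per-reach sediment capacity (L) and exchange coefficient (L/h)
  std::vector<double> cap_sed(n), Ex(n), sed_dry_kg(n);
  for (int i = 0; i < n; ++i) {
    double a_bed = bw[i] * len[i];               // m^2
    double v_sed = a_bed * sed_depth;            // m^3
    cap_sed[i] = 1000.0 * v_sed * (poros + rho_b * koc * foc_sed);
    Ex[i] = vex / 24.0 * a_bed * 1000.0;
    sed_dry_kg[i] = rho_b * 1000.0 * v_sed;      // kg dry sediment
  }

  // optional externally supplied per-reach hydrology (n x n_hours)
  bool external_hydro = Q_ext.isNotNull() && V_ext.isNotNull();
  NumericMatrix Qm, Vm;
  if (external_hydro) {
    Qm = NumericMatrix(Q_ext); Vm = NumericMatrix(V_ext);
    if (Qm.nrow() != n || Vm.nrow() != n || Qm.ncol() != n_hours ||
        Vm.ncol() != n_hours) {
      stop("external hydrology matrices must be n_reaches x n_hours");
    }
  }

  std::vector<double> W(n, 0.0), S(n, 0.0), inflow(n, 0.0);
  std::vector<double> prevQ(n, -1.0), prevD(n, 0.0);
  NumericMatrix cw(n, n_out);
  NumericMatrix cs = keep_sediment ? NumericMatrix(n, n_out)
                                   : NumericMatrix(0, 0);

  double led_in = 0.0, led_degw = 0.0, led_degs = 0.0, led_vol = 0.0,
         led_out = 0.0;

  int ev = 0;
  const int n_ev = drift_hour.size();

  for (int h = 0; h < n_hours; ++h) {
    int day = h / 24;
    double TK = temp_day[day] + 273.15;
    double arr = std::exp(-Ea / Rgas * (1.0 / TK - 1.0 / Tref));
    double kdegw = kdegw_ref * arr, kdegs = kdegs_ref * arr;

    std::fill(inflow.begin(), inflow.end(), 0.0);
    // drift deposited this hour
    for (; ev < n_ev && drift_hour[ev] == h; ++ev) {
      inflow[drift_reach[ev]] += drift_mass[ev];
      led_in += drift_mass[ev];
    }
    double qo = q_outlet[h];

    for (int k = 0; k < n; ++k) {
      int i = topo[k];
      double Q, V;
      if (external_hydro) {
        Q = Qm(i, h); V = Vm(i, h);
        if (V <= 0.0) stop("external hydrology: volume must be > 0");
      } else {
        Q = qo * area_ratio[i];
        double d;
        if (Q == prevQ[i]) {
          d = prevD[i];
        } else {
          d = manning_depth_one(Q, bw[i], bs[i], mn[i], sl[i], floor_depth,
                                depth_tol, depth_max);
          prevQ[i] = Q; prevD[i] = d;
        }
        double A = d * (bw[i] + bs[i] * d);
        V = A * len[i];                      // m^3, > 0 via depth floor
      }
      double cap_w = V * 1000.0;             // L
      double kadv = Q / V;                   // 1/h

      double alpha = kadv + kdegw + kvol_h + Ex[i] * fd / cap_w;
      double beta = Ex[i] / cap_sed[i];
      double gamma = Ex[i] * fd / cap_w;
      double delta = Ex[i] / cap_sed[i] + kdegs;

      double W0 = W[i] + inflow[i];
      StepOut o = linear_step(W0, S[i], alpha, beta, gamma, delta, 1.0);

      double outflow = kadv * o.Iw;
      led_degw += kdegw * o.Iw;
      led_vol += kvol_h * o.Iw;
      led_degs += kdegs * o.Is;
      int dn = down[i];
      if (dn >= 0) inflow[dn] += outflow; else led_out += outflow;

      W[i] = o.W1; S[i] = o.S1;
      if (h >= assess_start_hour) {
        cw(i, h - assess_start_hour) = o.Iw / cap_w; // hourly mean, ug/L
        if (keep_sediment) {
          cs(i, h - assess_start_hour) = o.Is / sed_dry_kg[i]; // ug/kg
        }
      }
    }
    if (h % 8760 == 0) Rcpp::checkUserInterrupt();
  }

  double stored = 0.0;
  for (int i = 0; i < n; ++i) stored += W[i] + S[i];

  return List::create(
    _["cw"] = cw,
    _["csed"] = cs,
    _["water_mass"] = NumericVector(W.begin(), W.end()),
    _["sediment_mass"] = NumericVector(S.begin(), S.end()),
    _["input"] = led_in, _["degraded_water"] = led_degw,
    _["degraded_sediment"] = led_degs, _["volatilized"] = led_vol,
    _["exported_at_outlet"] = led_out, _["stored"] = stored);
}
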