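#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP c_param_names(void);
SEXP c_state_names(void);
SEXP c_aux_names(void);
SEXP c_eval(SEXP, SEXP, SEXP);

static const R_CallMethodDef call_entries[] = {
  {"c_param_names", (DL_FUNC) &c_param_names, 0},
  {"c_state_names", (DL_FUNC) &c_state_names, 0},
  {"c_aux_names",   (DL_FUNC) &c_aux_names,   0},
  {"c_eval",        (DL_FUNC) &c_eval,        3},
  {NULL, NULL, 0}
};

void R_init_ttmyo(DllInfo *dll)
{
  R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
  /* deSolve looks up c_initmod/c_derivs by name */
  R_useDynamicSymbols(dll, TRUE);
}
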