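(((((Host_0004:0.09439772914,Host_0007:0.09439772914):0.0199707517,Host_0003:0.1143684808):1.320882736,((Host_0008:0.6520768817,(Host_0001:0.5171561717,(Host_0002:0.1574064955,Host_0005:0.1574064955):0.3597496763):0.13492071):0.08780677105,Host_0006:0.7398836528):0.6953675644):1,(((Host_0014:1.163466646,(Host_0011:0.6905635954,Host_0015:0.6905635954):0.4729030506):0.1414663811,(Host_0010:0.5529917772,Host_0016:0.5529917772):0.75194125):0.7621731167,((Host_0009:0.5814391559,Host_0013:0.5814391559):1.114597907,Host_0012:1.696037062):0.3710690814):1):1,(((((Host_0018:0.004658565798,Host_0023:0.004658565798):0.3234925114,(Host_0024:0.03373147295,Host_0019:0.03373147295):0.2944196043):0.06758003813,Host_0022:0.3957311154):0.1416764525,Host_0021:0.5374075678):0.257087148,(Host_0020:0.1225016965,Host_0017:0.1225016965):0.6719930194):1);
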